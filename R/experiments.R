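# Emulation of classical conditioning experiments.  Conditioning clamps the
# belief through the corresponding (approach, signal) updates -- the agent
# experiences a defined environmental state -- and testing applies the policy
# once per agent with freshly drawn costs.  Because the belief trajectory is
# deterministic given the protocol, a forgetting curve is a binomial
# functional of a single trajectory; the exact fraction (Laplace CDF at the
# policy threshold) is reported alongside the Monte-Carlo one.

#' Standard conditioning protocols
#'
#' * `single_appetitive`, `single_aversive`: one conditioning event.
#' * `spaced`: six aversive events separated by waiting periods of 9 time
#'   bins (event times 0, 10, ..., 50).
#' * `massed`: six aversive events in consecutive bins (times 0..5).
#' * `reversal`: punishing, neutral, punishing in consecutive bins.
#'
#' @param name protocol name.
#' @return An object of class `protocol`: a data frame of `(time, event)`
#'   rows with the protocol name attached.
#' @export
make_protocol <- function(name = c("single_appetitive", "single_aversive",
                                   "spaced", "massed", "reversal")) {
  name <- match.arg(name)
  events <- switch(name,
    single_appetitive = data.frame(time = 0, event = "appetitive"),
    single_aversive = data.frame(time = 0, event = "aversive"),
    spaced = data.frame(time = seq(0, 50, by = 10), event = "aversive"),
    massed = data.frame(time = 0:5, event = "aversive"),
    reversal = data.frame(time = 0:2,
                          event = c("aversive", "neutral", "aversive")))
  stopifnot(all(diff(events$time) > 0), all(events$time >= 0))
  structure(events, name = name, class = c("protocol", "data.frame"))
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<%s protocol: %d events>\n", attr(x, "name"), nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Conditioned response of a protocol
#'
#' Approach after appetitive conditioning, avoid after aversive; the last
#' non-neutral event decides.
#'
#' @param protocol a `protocol`.
#' @return `"ap"` or `"av"`.
#' @export
conditioned_response <- function(protocol) {
  ev <- protocol$event[protocol$event != "neutral"]
  if (!length(ev)) stop("protocol has no conditioning event")
  if (ev[length(ev)] == "appetitive") "ap" else "av"
}

#' Belief at the end of a conditioning protocol
#'
#' Applies the protocol's clamped conditioning events to the belief, with
#' drift (avoid-equivalent updates) during the waiting bins between events.
#' Each event occupies one time bin.  On an extended environment every
#' waiting bin expands to `time_refinement` extended bins while each event
#' still occupies a single extended bin.
#'
#' @param protocol a `protocol`.
#' @param env environment object.
#' @param b0 belief before training; defaults to the stationary belief.
#' @return The post-training belief.
#' @export
protocol_belief <- function(protocol, env, b0 = stationary_belief(env)) {
  refine <- if (inherits(env, "ext_env_params")) env$time_refinement else 1L
  b <- b0
  times <- protocol$time
  for (i in seq_len(nrow(protocol))) {
    if (i > 1) {
      waiting <- times[i] - times[i - 1] - 1
      if (waiting > 0) b <- drift(b, waiting * refine, env)
    }
    b <- conditioned_belief(protocol$event[i], env, b)
  }
  b
}

#' Default delay grid for forgetting curves
#'
#' Zero plus log-spaced delays up to `max_delay` basic time bins.
#'
#' @param max_delay largest delay.
#' @param n number of grid points.
#' @return Sorted integer vector of delays.
#' @export
default_delays <- function(max_delay = 200, n = 21) {
  unique(c(0, round(exp(seq(0, log(max_delay), length.out = n - 1)))))
}

#' Forgetting curve of a policy after a conditioning protocol
#'
#' Runs the protocol's belief clamping, drifts the belief through each test
#' delay, and at every delay lets `n_agents` agents decide once with
#' independently drawn costs of responding.  The fraction emitting the
#' conditioned response is returned with its binomial standard error; the
#' exact fraction implied by the policy threshold and the Laplace cost law is
#' included as well, along with the large-delay asymptote computed directly
#' at the stationary belief.
#'
#' For policies that do not drift (the `no_forgetting` baseline) the tested
#' belief is the post-training belief at every delay.
#'
#' @param policy a `policy` object.
#' @param protocol a `protocol`, or its name.
#' @param env environment object (basic or extended; delays are always in
#'   basic time bins).
#' @param costs a `cost_model`.
#' @param delays vector of test delays in basic time bins.
#' @param n_agents number of simulated agents per delay.
#' @return An object of class `forgetting_curve`: a data frame with columns
#'   `delay`, `fraction_cr`, `stderr`, `fraction_exact`, plus attributes
#'   `n_agents`, `conditioned_response`, `asymptote` and names of policy and
#'   protocol.
#' @export
forgetting_curve <- function(policy, protocol, env, costs,
                             delays = default_delays(), n_agents = 2000) {
  if (is.character(protocol)) protocol <- make_protocol(protocol)
  stopifnot(n_agents >= 1)
  refine <- if (inherits(env, "ext_env_params")) env$time_refinement else 1L
  cr <- conditioned_response(protocol)
  b_train <- protocol_belief(protocol, env)
  delays <- sort(unique(delays))

  drifting <- !isFALSE(policy$drifts)
  b <- b_train
  prev <- 0
  frac <- se <- exact <- numeric(length(delays))
  for (i in seq_along(delays)) {
    steps <- (delays[i] - prev) * refine
    if (steps > 0 && drifting) b <- drift(b, steps, env)
    prev <- delays[i]
    cs <- sample_costs(costs, n_agents)
    acts <- decide(policy, b, cs$c_ap, cs$c_av)
    f <- mean(acts == cr)
    frac[i] <- f
    se[i] <- sqrt(f * (1 - f) / n_agents)
    p_ap <- .ap_prob(policy, b, costs)
    exact[i] <- if (cr == "ap") p_ap else 1 - p_ap
  }

  p_ap_inf <- .ap_prob(policy, stationary_belief(env), costs)
  asym <- if (cr == "ap") p_ap_inf else 1 - p_ap_inf
  if (!drifting) asym <- exact[1]

  structure(data.frame(delay = delays, fraction_cr = frac, stderr = se,
                       fraction_exact = exact),
            n_agents = n_agents, conditioned_response = cr,
            asymptote = asym, policy = policy$name,
            protocol = attr(protocol, "name"),
            class = c("forgetting_curve", "data.frame"))
}

#' @export
print.forgetting_curve <- function(x, ...) {
  cat(sprintf("Forgetting curve: %s protocol, %s policy, %d agents/point\n",
              attr(x, "protocol"), attr(x, "policy"), attr(x, "n_agents")))
  cat(sprintf("  conditioned response: %s, asymptote %.3f\n",
              attr(x, "conditioned_response"), attr(x, "asymptote")))
  print.data.frame(cbind(x[, c("delay", "fraction_cr", "stderr")],
                         exact = round(x$fraction_exact, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.forgetting_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add)
    graphics::plot(x$delay, x$fraction_cr, ylim = c(0, 1), type = "n",
                   xlab = "delay (time bins)",
                   ylab = "fraction conditioned response", ...)
  graphics::points(x$delay, x$fraction_cr, col = col, pch = 16)
  graphics::arrows(x$delay, x$fraction_cr - x$stderr,
                   x$delay, x$fraction_cr + x$stderr,
                   angle = 90, code = 3, length = 0.02, col = col)
  graphics::lines(x$delay, x$fraction_exact, col = col)
  graphics::abline(h = attr(x, "asymptote"), lty = 3, col = col)
  invisible(x)
}

#' Delay at which a forgetting curve has covered half its gap
#'
#' The half-gap delay is where the curve first crosses the midpoint between
#' its initial value and its large-delay asymptote, found by linear
#' interpolation on the delay grid.
#'
#' @param curve a `forgetting_curve`.
#' @param use `"exact"` (noise-free fractions; default) or `"mc"`.
#' @return The half-gap delay, or `NA` if the curve never crosses.
#' @export
half_gap_delay <- function(curve, use = c("exact", "mc")) {
  use <- match.arg(use)
  f <- if (use == "exact") curve$fraction_exact else curve$fraction_cr
  d <- curve$delay
  target <- (f[1] + attr(curve, "asymptote")) / 2
  sgn <- sign(f - target)
  cross <- which(sgn[-1] != sgn[-length(sgn)])[1]
  if (is.na(cross)) return(NA_real_)
  i <- cross
  if (f[i + 1] == f[i]) return(d[i])
  d[i] + (target - f[i]) / (f[i + 1] - f[i]) * (d[i + 1] - d[i])
}

#' Forgetting asymmetry after appetitive versus aversive conditioning
#'
#' With symmetric chain rates any asymmetry between the two single-event
#' forgetting curves must come from the policy.  The provident policy values
#' the information gained by approaching, so it abandons the aversive
#' (uninformative) response sooner: its aversive half-gap delay is smaller
#' than the appetitive one, while the greedy policy treats both memories
#' symmetrically.
#'
#' @param env environment object; must have symmetric leaving rates
#'   (`a_rn == a_pn`).
#' @param costs a `cost_model`.
#' @param policy the policy to test; defaults to the provident policy with
#'   configuration `dp_cfg`.
#' @param dp_cfg a [dp_config()] used when `policy` is `NULL`.
#' @param delays delay grid.
#' @param n_agents agents per delay.
#' @return List with the two `forgetting_curve`s (`appetitive`, `aversive`)
#'   and the named `half_gap` delays computed from the exact fractions.
#' @export
asymmetry_experiment <- function(env, costs, policy = NULL,
                                 dp_cfg = dp_config(),
                                 delays = default_delays(),
                                 n_agents = 2000) {
  if (!isTRUE(all.equal(env$a_rn, env$a_pn)))
    stop("asymmetry experiment requires symmetric leaving rates a_rn == a_pn")
  if (is.null(policy)) policy <- provident_policy(env, costs, dp_cfg)
  app <- forgetting_curve(policy, "single_appetitive", env, costs,
                          delays, n_agents)
  ave <- forgetting_curve(policy, "single_aversive", env, costs,
                          delays, n_agents)
  list(appetitive = app, aversive = ave,
       half_gap = c(appetitive = half_gap_delay(app),
                    aversive = half_gap_delay(ave)),
       policy = policy$name)
}

#' Forgetting after spaced, massed and reversal training in the extended
#' environment
#'
#' Six-state filtering through each protocol, then greedy decisions on the
#' drifted belief.  Spaced training -- surviving punishment evidence across
#' long gaps -- is informative about the slow volatility mode; reversal
#' training, which requires two quick state flips, is informative about the
#' fast mode.  The inferred mode in turn sets the forgetting speed.
#'
#' @param ext_env an `ext_env_params`.
#' @param costs a `cost_model`.
#' @param delays delay grid in basic time bins.
#' @param n_agents agents per delay.
#' @param protocols protocol names to run.
#' @return List with `curves` (named list of `forgetting_curve`s),
#'   `slow_posterior` (probability of the slow mode immediately after
#'   training, per protocol) and `half_gap` (per protocol, exact fractions).
#' @export
extended_forgetting <- function(ext_env, costs, delays = default_delays(),
                                n_agents = 2000,
                                protocols = c("spaced", "massed", "reversal")) {
  policy <- greedy_policy(ext_env)
  curves <- list()
  slow_post <- half_gap <- stats::setNames(numeric(length(protocols)),
                                           protocols)
  for (pn in protocols) {
    prot <- make_protocol(pn)
    b_train <- protocol_belief(prot, ext_env)
    slow_post[pn] <- meta_posterior(b_train)["slow"]
    cv <- forgetting_curve(policy, prot, ext_env, costs, delays, n_agents)
    curves[[pn]] <- cv
    half_gap[pn] <- half_gap_delay(cv)
  }
  list(curves = curves, slow_posterior = slow_post, half_gap = half_gap)
}

#' Test-retest consistency of the conditioned response
#'
#' Agents sharing one belief are tested once, grouped by their first
#' response, and each group is immediately retested with freshly drawn
#' costs.  Because the belief is a sufficient statistic and the costs are
#' independent across tests, both groups show the conditioned response at
#' the same rate on retest.
#'
#' @param policy a `policy`.
#' @param b the shared belief at test time.
#' @param costs a `cost_model`.
#' @param n_agents number of agents.
#' @param conditioned `"ap"` or `"av"`: which response counts as conditioned.
#' @return List with the first-test fraction, the per-group retest fractions
#'   and standard errors, and the group sizes.
#' @export
retest_experiment <- function(policy, b, costs, n_agents = 4000,
                              conditioned = "av") {
  cs1 <- sample_costs(costs, n_agents)
  first <- decide(policy, b, cs1$c_ap, cs1$c_av) == conditioned
  cs2 <- sample_costs(costs, n_agents)
  second <- decide(policy, b, cs2$c_ap, cs2$c_av) == conditioned
  grp <- split(second, first)
  frac <- vapply(grp, mean, numeric(1))
  n <- vapply(grp, length, numeric(1))
  list(first_fraction = mean(first),
       retest_fraction = frac,
       retest_se = sqrt(frac * (1 - frac) / n),
       group_sizes = n)
}
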