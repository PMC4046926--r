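# A simple approximative implementation of the belief-based agent: two
# synaptic strengths, one per action channel, that decay exponentially toward
# a baseline in the absence of feedback and are reset in a Hebbian
# (reward) or anti-Hebbian (punishment) way.  Decisions compare the strength
# difference against a Laplace noise draw, the same law as the cost
# difference of the belief-based agent.

#' Parameters of the mechanistic two-synapse agent
#'
#' @param alpha_ap,alpha_av per-bin relaxation rates of the approach and
#'   avoid channel toward their baselines, in `[0, 1]`.  A provident-like
#'   agent uses `alpha_av > alpha_ap` (the avoid memory decays faster); a
#'   greedy-like agent uses equal rates.
#' @param w_base_ap,w_base_av baseline synaptic strengths (>= 0).
#' @param w_max_ap,w_max_av reset values after reward / punishment; must not
#'   be below the corresponding baseline.
#' @param noise_scale scale of the Laplace decision noise, in the same units
#'   as the strengths.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(alpha_ap, alpha_av, w_base_ap, w_base_av,
                        w_max_ap, w_max_av, noise_scale = 0.1) {
  if (any(c(alpha_ap, alpha_av) < 0) || any(c(alpha_ap, alpha_av) > 1))
    stop("decay rates must lie in [0, 1]")
  if (w_base_ap < 0 || w_base_av < 0)
    stop("baselines must be nonnegative")
  if (w_max_ap < w_base_ap || w_max_av < w_base_av)
    stop("reset values must not be below the baselines")
  if (noise_scale <= 0) stop("noise_scale must be positive")
  structure(list(alpha_ap = alpha_ap, alpha_av = alpha_av,
                 w_base_ap = w_base_ap, w_base_av = w_base_av,
                 w_max_ap = w_max_ap, w_max_av = w_max_av,
                 noise_scale = noise_scale),
            class = "mech_params")
}

#' Current synaptic strengths of the mechanistic agent
#' @param w_ap,w_av strengths of the approach and avoid channel.
#' @return An object of class `mech_state`.
#' @export
mech_state <- function(w_ap, w_av) {
  structure(list(w_ap = w_ap, w_av = w_av), class = "mech_state")
}

#' One update of the mechanistic agent
#'
#' Without feedback each strength relaxes one step toward its baseline,
#' `w <- w + alpha * (w_base - w)`.  Reward resets the approach strength to
#' its maximum and the avoid strength to zero; punishment does the mirror
#' image.
#'
#' @param state a `mech_state`.
#' @param event `"none"`, `"reward"` or `"punishment"`.
#' @param params a `mech_params`.
#' @return The updated `mech_state`.
#' @export
mech_update <- function(state, event = c("none", "reward", "punishment"),
                        params) {
  event <- match.arg(event)
  switch(event,
    none = mech_state(
      state$w_ap + params$alpha_ap * (params$w_base_ap - state$w_ap),
      state$w_av + params$alpha_av * (params$w_base_av - state$w_av)),
    reward = mech_state(params$w_max_ap, 0),
    punishment = mech_state(0, params$w_max_av))
}

#' Decision of the mechanistic agent
#'
#' Approach exactly when `w_ap - w_av + noise > 0`.
#'
#' @param state a `mech_state`.
#' @param noise_draw numeric vector of noise draws (one decision each).
#' @return Character vector of `"ap"` / `"av"`.
#' @export
mech_decide <- function(state, noise_draw) {
  ifelse(state$w_ap - state$w_av + noise_draw > 0, "ap", "av")
}

# exact strength difference trajectory after a conditioning event
.mech_diff_after <- function(params, event, delays) {
  rho_ap <- (1 - params$alpha_ap)^delays
  rho_av <- (1 - params$alpha_av)^delays
  if (event == "reward") {
    w_ap <- params$w_base_ap + (params$w_max_ap - params$w_base_ap) * rho_ap
    w_av <- params$w_base_av * (1 - rho_av)
  } else {
    w_ap <- params$w_base_ap * (1 - rho_ap)
    w_av <- params$w_base_av + (params$w_max_av - params$w_base_av) * rho_av
  }
  w_ap - w_av
}

#' Exact forgetting curve of the mechanistic agent
#'
#' After a single reward or punishment reset, the strengths decay
#' geometrically, so the probability of the conditioned response at delay `k`
#' is the Laplace CDF evaluated at the closed-form strength difference.
#'
#' @param params a `mech_params`.
#' @param event `"reward"` or `"punishment"` (the conditioning event).
#' @param delays vector of delays in time bins.
#' @return Data frame with `delay` and `fraction_cr`, the exact probability
#'   of the conditioned response (approach after reward, avoid after
#'   punishment).
#' @export
mech_forgetting_curve <- function(params, event = c("reward", "punishment"),
                                  delays) {
  event <- match.arg(event)
  d <- .mech_diff_after(params, event, delays)
  noise <- cost_model(params$noise_scale)
  p_ap <- 1 - laplace_diff_cdf(-d, noise)
  data.frame(delay = delays,
             fraction_cr = if (event == "reward") p_ap else 1 - p_ap)
}

# pack/unpack for the bounded search: decay rates through a logit, strengths
# through a log, maxima as baseline + positive amplitude
.mech_pack <- function(p, mode) {
  th <- c(stats::qlogis(p$alpha_ap),
          log(p$w_base_ap + 1e-8), log(p$w_base_av + 1e-8),
          log(p$w_max_ap - p$w_base_ap + 1e-8),
          log(p$w_max_av - p$w_base_av + 1e-8))
  if (mode == "provident") th <- c(th, stats::qlogis(p$alpha_av))
  th
}

.mech_unpack <- function(th, mode, noise_scale) {
  alpha_ap <- stats::plogis(th[1])
  alpha_av <- if (mode == "provident") stats::plogis(th[6]) else alpha_ap
  w_base_ap <- exp(th[2]); w_base_av <- exp(th[3])
  mech_params(alpha_ap, alpha_av, w_base_ap, w_base_av,
              w_base_ap + exp(th[4]), w_base_av + exp(th[5]),
              noise_scale)
}

#' Fit the mechanistic agent to a pair of forgetting curves
#'
#' Least-squares fit of the agent's exact appetitive and aversive forgetting
#' curves to target curves on a common delay grid, by Nelder-Mead search on
#' transformed (bound-respecting) parameters from Latin-hypercube-seeded
#' restarts.  In `"greedy"` mode the two decay rates are constrained to be
#' equal; in `"provident"` mode they are free.
#'
#' @param appetitive,aversive target curves: data frames with columns
#'   `delay` and `fraction_cr` (fraction of agents showing the conditioned
#'   response), e.g. produced by [forgetting_curve()].
#' @param mode `"provident"` or `"greedy"`.
#' @param noise_scale Laplace scale of the decision noise, fixed during the
#'   fit so that the mechanistic and the belief-based agent face the same
#'   decision stochasticity.
#' @param n_restarts number of local searches.
#' @return An object of class `mech_fit` with elements `params`
#'   (a `mech_params`), `rmse`, `mode`, `convergence` and the per-restart
#'   objective values.  `coef()` returns the fitted parameters.
#' @export
fit_mech_params <- function(appetitive, aversive,
                            mode = c("provident", "greedy"),
                            noise_scale = 0.1, n_restarts = 10) {
  mode <- match.arg(mode)
  stopifnot(identical(appetitive$delay, aversive$delay))
  delays <- appetitive$delay
  target <- c(appetitive$fraction_cr, aversive$fraction_cr)

  objective <- function(th) {
    p <- try(.mech_unpack(th, mode, noise_scale), silent = TRUE)
    if (inherits(p, "try-error")) return(1e6)
    pred <- c(mech_forgetting_curve(p, "reward", delays)$fraction_cr,
              mech_forgetting_curve(p, "punishment", delays)$fraction_cr)
    sum((pred - target)^2)
  }

  d <- if (mode == "provident") 6L else 5L
  seeds <- lhs::randomLHS(n_restarts, d)
  # map unit hypercube to plausible starting ranges
  starts <- t(apply(seeds, 1, function(u) {
    alpha1 <- stats::qlogis(0.002 + u[1] * 0.3)
    s <- c(alpha1,
           log(0.01 + u[2] * 0.8), log(0.01 + u[3] * 0.8),
           log(0.05 + u[4] * 2), log(0.05 + u[5] * 2))
    if (d == 6L) s <- c(s, stats::qlogis(0.002 + u[6] * 0.3))
    s
  }))

  best <- NULL
  vals <- numeric(n_restarts)
  for (i in seq_len(n_restarts)) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-10))
    vals[i] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the winner until the simplex converges
  for (round in 1:5) {
    if (best$convergence == 0) break
    best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-10))
  }

  params <- .mech_unpack(best$par, mode, noise_scale)
  rmse <- sqrt(best$value / length(target))
  if (best$convergence != 0)
    warning("fit did not fully converge; best parameters returned")
  structure(list(params = params, rmse = rmse, mode = mode,
                 convergence = best$convergence, restart_values = vals,
                 delays = delays, target = target),
            class = "mech_fit")
}

#' @export
coef.mech_fit <- function(object, ...) {
  p <- object$params
  c(alpha_ap = p$alpha_ap, alpha_av = p$alpha_av,
    w_base_ap = p$w_base_ap, w_base_av = p$w_base_av,
    w_max_ap = p$w_max_ap, w_max_av = p$w_max_av,
    noise_scale = p$noise_scale)
}

#' @export
print.mech_fit <- function(x, ...) {
  cat(sprintf("Mechanistic agent fit (%s mode), RMSE %.4f\n", x$mode, x$rmse))
  print(round(coef(x), 4))
  invisible(x)
}

#' Predicted forgetting curves of a fitted mechanistic agent
#' @param object a `mech_fit`.
#' @param delays delay grid; defaults to the grid used in the fit.
#' @param ... unused.
#' @return List with `appetitive` and `aversive` exact curves.
#' @export
predict.mech_fit <- function(object, delays = object$delays, ...) {
  list(appetitive = mech_forgetting_curve(object$params, "reward", delays),
       aversive = mech_forgetting_curve(object$params, "punishment", delays))
}
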