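# Hidden Markov reward environment: a stimulus is associated with one of three
# states -- rewarding (r), neutral (n), punishing (p) -- that change slowly over
# time.  An extended variant adds a hidden slow/fast volatility mode.

#' State and signal labels of the basic environment
#'
#' The basic environment has three hidden states: `r` (approaching yields
#' reward), `n` (neutral) and `p` (approaching yields punishment).
#' Reinforcement signals are `"+"`, `"0"` and `"-"`.
#' @keywords internal
#' @name forgetsim-conventions
NULL

.STATES <- c("r", "n", "p")
.SIGNALS <- c("+", "0", "-")
.ACTIONS <- c("ap", "av")

#' Parameters of the basic three-state environment
#'
#' Per-time-bin transition probabilities of the hidden state, reinforcement
#' magnitudes, and the emission probabilities of the neutral state under
#' approach.  Direct transitions between the rewarding and the punishing state
#' are excluded by construction: a switch always passes through the neutral
#' state.
#'
#' @param a_rn probability of leaving the rewarding for the neutral state
#'   within one time bin.
#' @param a_nr probability of a neutral-to-rewarding transition.
#' @param a_np probability of a neutral-to-punishing transition.
#' @param a_pn probability of leaving the punishing for the neutral state.
#' @param reward_pos reinforcement magnitude of the positive signal `"+"`.
#' @param reward_neg reinforcement magnitude of the negative signal `"-"`
#'   (conventionally negative).
#' @param emit_n length-3 probability vector (named `+`, `0`, `-`) of the
#'   reinforcement signal when approaching in the neutral state.  The default
#'   `c(0.005, 0.99, 0.005)` leaves a small chance of stimulus-unrelated
#'   reward or punishment.
#'
#' @return An object of class `env_params`.
#' @examples
#' env <- env_params(a_rn = 0.05, a_nr = 0.005, a_np = 0.005, a_pn = 0.05)
#' transition_matrix(env)
#' @export
env_params <- function(a_rn, a_nr, a_np, a_pn,
                       reward_pos = 1, reward_neg = -1,
                       emit_n = c("+" = 0.005, "0" = 0.99, "-" = 0.005)) {
  rates <- c(a_rn = a_rn, a_nr = a_nr, a_np = a_np, a_pn = a_pn)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("transition rates must lie in [0, 1]")
  if (a_nr + a_np > 1)
    stop("a_nr + a_np exceeds 1: the neutral row would not be stochastic")
  emit_n <- as.numeric(emit_n)
  if (length(emit_n) != 3 || any(emit_n < 0) || abs(sum(emit_n) - 1) > 1e-12)
    stop("emit_n must be three nonnegative probabilities summing to 1")
  structure(list(a_rn = a_rn, a_nr = a_nr, a_np = a_np, a_pn = a_pn,
                 reward_pos = reward_pos, reward_neg = reward_neg,
                 emit_n = stats::setNames(emit_n, .SIGNALS)),
            class = "env_params")
}

#' Default environment used throughout the package
#'
#' Symmetric rates `a_rn = a_pn = 0.04` (mean dwell time of 25 bins in a
#' conditioned state) and `a_nr = a_np = 0.08`, giving zero average reward
#' and a stationary distribution `(0.4, 0.2, 0.4)`.  In this regime the
#' stimulus is predictive most of the time, so tracking the association pays:
#' the attainable reward rate is clearly positive and the information gained
#' by approaching has substantial economic value, which is the regime the
#' model's provident-versus-greedy comparison is about.
#'
#' @return An `env_params` object.
#' @export
default_env_params <- function() {
  env_params(a_rn = 0.04, a_nr = 0.08, a_np = 0.08, a_pn = 0.04)
}

#' @export
print.env_params <- function(x, ...) {
  cat("Basic 3-state environment (r, n, p)\n")
  cat(sprintf("  rates: a_rn=%g a_nr=%g a_np=%g a_pn=%g\n",
              x$a_rn, x$a_nr, x$a_np, x$a_pn))
  cat(sprintf("  reinforcement: +%g / %g, neutral-state emissions (%s)\n",
              x$reward_pos, x$reward_neg,
              paste(signif(x$emit_n, 3), collapse = ", ")))
  rp <- rates_to_reparam(x)
  cat(sprintf("  stationary: p_n=%.4f, average reward rho=%.4f\n",
              rp$p_n, rp$rho))
  invisible(x)
}

#' One-step transition matrix of an environment
#'
#' @param env an `env_params` or `ext_env_params` object.
#' @param ... unused.
#' @return A row-stochastic matrix over the hidden states (3x3 for the basic
#'   model, 6x6 for the extended model).  Entries between `r` and `p` are
#'   exactly zero in the basic model.
#' @export
transition_matrix <- function(env, ...) UseMethod("transition_matrix")

#' @export
transition_matrix.env_params <- function(env, ...) {
  P <- rbind(c(1 - env$a_rn, env$a_rn, 0),
             c(env$a_nr, 1 - env$a_nr - env$a_np, env$a_np),
             c(0, env$a_pn, 1 - env$a_pn))
  dimnames(P) <- list(.STATES, .STATES)
  P
}

#' Emission probabilities of the reinforcement signal
#'
#' Rows are hidden states, columns the signals `+`, `0`, `-`.  Avoiding is
#' uninformative: the neutral signal is returned with certainty in every
#' state.  Approaching yields `+` with certainty in `r`, `-` with certainty
#' in `p`, and the `emit_n` mixture in `n`.
#'
#' @param env an `env_params` or `ext_env_params` object.
#' @param action `"ap"` (approach) or `"av"` (avoid).
#' @return A states-by-signals probability matrix with unit row sums.
#' @export
emission_matrix <- function(env, action = c("ap", "av")) {
  UseMethod("emission_matrix")
}

#' @export
emission_matrix.env_params <- function(env, action = c("ap", "av")) {
  action <- match.arg(action)
  if (action == "av") {
    E <- matrix(rep(c(0, 1, 0), each = 3), nrow = 3)
  } else {
    E <- rbind(c(1, 0, 0), env$emit_n, c(0, 0, 1))
  }
  dimnames(E) <- list(.STATES, .SIGNALS)
  E
}

#' Numeric value of each reinforcement signal
#' @param env an `env_params` or `ext_env_params` object.
#' @return Named vector with the reward magnitudes of `+`, `0`, `-`.
#' @export
signal_values <- function(env) {
  if (inherits(env, "ext_env_params")) env <- env$base_slow
  c("+" = env$reward_pos, "0" = 0, "-" = env$reward_neg)
}

# reachability check used to reject reducible chains
.is_irreducible <- function(P) {
  n <- nrow(P)
  R <- (P > 0) | diag(n) > 0
  for (i in seq_len(ceiling(log2(n)) + 1)) R <- (R %*% R) > 0
  all(R)
}

#' Stationary distribution of a Markov chain
#'
#' Solves the self-consistency equation `pi P = pi` with the normalization
#' `sum(pi) = 1` by a direct linear solve.
#'
#' @param P a row-stochastic transition matrix, or an `env_params` /
#'   `ext_env_params` object whose transition matrix is used.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  if (inherits(P, c("env_params", "ext_env_params"))) P <- transition_matrix(P)
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix")
  if (any(abs(rowSums(P) - 1) > 1e-10) || any(P < -1e-14))
    stop("P must be row-stochastic")
  if (!.is_irreducible(P))
    stop("chain is reducible; the stationary distribution is not unique")
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- as.numeric(qr.solve(A, b))
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (max(abs(pi %*% P - pi)) > 1e-12)
    stop("stationary solve failed to satisfy pi P = pi")
  stats::setNames(pi, rownames(P))
}

#' Re-parametrize the environment by neutral-state probability, average
#' reward and timescale
#'
#' Instead of the four transition rates, the environment can be described by
#' the stationary probability `p_n` of the neutral state, the average reward
#' `rho = reward_pos * pi_r + reward_neg * pi_p` collected when approaching at
#' stationarity, and the rate of leaving a conditioned state, whose inverse is
#' the mean number of time bins the environment dwells there.  The fourth
#' degree of freedom is fixed by a symmetry convention: both conditioned
#' states are left at `timescale_rate` unless `leave_p` overrides the rate of
#' leaving `p`.
#'
#' @param p_n stationary probability of the neutral state, in (0, 1).
#' @param rho average reward at stationarity (reward units per approach).
#' @param timescale_rate per-bin probability of leaving the rewarding state.
#' @param reward_pos,reward_neg reinforcement magnitudes.
#' @param leave_p optional asymmetric rate of leaving the punishing state.
#' @return An `env_params` object whose stationary distribution reproduces
#'   `(p_n, rho)`.
#' @seealso [rates_to_reparam()] for the inverse map.
#' @export
reparam_to_rates <- function(p_n, rho, timescale_rate,
                             reward_pos = 1, reward_neg = -1,
                             leave_p = timescale_rate) {
  if (p_n <= 0 || p_n >= 1) stop("p_n must lie strictly between 0 and 1")
  pi_r <- (rho - reward_neg * (1 - p_n)) / (reward_pos - reward_neg)
  pi_p <- 1 - p_n - pi_r
  if (pi_r < 0 || pi_p < 0)
    stop(sprintf(paste0("infeasible (p_n, rho): implied stationary ",
                        "probabilities pi_r=%.4f, pi_p=%.4f"), pi_r, pi_p))
  # detailed balance on the path r - n - p fixes the inward rates
  a_nr <- pi_r * timescale_rate / p_n
  a_np <- pi_p * leave_p / p_n
  if (a_nr + a_np > 1)
    stop("infeasible reparametrization: neutral row would not be stochastic")
  env_params(a_rn = timescale_rate, a_nr = a_nr, a_np = a_np, a_pn = leave_p,
             reward_pos = reward_pos, reward_neg = reward_neg)
}

#' Neutral-state probability, average reward and timescale of an environment
#'
#' @param env an `env_params` object.
#' @return List with `p_n`, `rho`, `timescale_rate` (= `a_rn`) and the full
#'   stationary distribution `pi`.
#' @export
rates_to_reparam <- function(env) {
  pi <- stationary_distribution(transition_matrix(env))
  list(p_n = unname(pi["n"]),
       rho = unname(env$reward_pos * pi["r"] + env$reward_neg * pi["p"]),
       timescale_rate = env$a_rn,
       pi = pi)
}

#' Draw reinforcement signals
#'
#' Samples the external reinforcement signal given hidden state(s) and an
#' action, using the current R random number generator.  Avoiding always
#' returns the neutral signal.
#'
#' @param state character vector of hidden states (`"r"`, `"n"`, `"p"`).
#' @param action a single action, `"ap"` or `"av"`.
#' @param env an `env_params` object.
#' @return Character vector of signals, one per state.
#' @export
emit_reinforcement <- function(state, action = c("ap", "av"), env) {
  action <- match.arg(action)
  state <- as.character(state)
  if (!all(state %in% .STATES)) stop("unknown environmental state")
  if (action == "av") return(rep("0", length(state)))
  out <- character(length(state))
  out[state == "r"] <- "+"
  out[state == "p"] <- "-"
  idx_n <- which(state == "n")
  if (length(idx_n))
    out[idx_n] <- sample(.SIGNALS, length(idx_n), replace = TRUE,
                         prob = env$emit_n)
  out
}

#' Simulate a state trajectory of the environment
#'
#' @param env an `env_params` or `ext_env_params` object.
#' @param n_steps number of transitions to simulate.
#' @param s0 initial state label; defaults to a draw from the stationary
#'   distribution.
#' @return Character vector of length `n_steps` holding the visited states
#'   (the state after each of the `n_steps` transitions from `s0`).
#' @export
sample_trajectory <- function(env, n_steps, s0 = NULL) {
  P <- transition_matrix(env)
  states <- rownames(P)
  if (is.null(s0)) s0 <- sample(states, 1, prob = stationary_distribution(P))
  if (!s0 %in% states) stop("s0 is not a state of this environment")
  if (n_steps == 0) return(character(0))
  cum <- t(apply(P, 1, cumsum))
  out <- character(n_steps)
  cur <- match(s0, states)
  u <- stats::runif(n_steps)
  for (t in seq_len(n_steps)) {
    cur <- findInterval(u[t], cum[cur, ], left.open = TRUE) + 1L
    out[t] <- states[cur]
  }
  out
}

#' Parameters of the extended six-state environment
#'
#' A hidden meta variable in state `slow` or `fast` controls the rate of
#' change of the reward state: conditional on the meta state the reward state
#' follows `base_slow` or `base_fast`.  Within one time bin the meta
#' transition and the reward-state transition are independent (product
#' kernel).  The extended model uses a finer time discretization:
#' `time_refinement` extended bins correspond to one bin of the basic model.
#'
#' @param base_slow,base_fast `env_params` for the two meta states; must share
#'   reinforcement magnitudes and emission probabilities.
#' @param q_sf,q_fs per-extended-bin meta transition probabilities
#'   slow-to-fast and fast-to-slow.
#' @param time_refinement integer number of extended bins per basic bin.
#' @return An object of class `ext_env_params`.
#' @export
ext_env_params <- function(base_slow, base_fast, q_sf = 0.001, q_fs = 0.001,
                           time_refinement = 10) {
  stopifnot(inherits(base_slow, "env_params"), inherits(base_fast, "env_params"))
  if (q_sf < 0 || q_sf > 1 || q_fs < 0 || q_fs > 1)
    stop("meta transition rates must lie in [0, 1]")
  if (base_fast$a_rn <= base_slow$a_rn || base_fast$a_pn <= base_slow$a_pn)
    stop("fast mode must leave conditioned states at strictly larger rates")
  if (!isTRUE(all.equal(base_slow$emit_n, base_fast$emit_n)) ||
      base_slow$reward_pos != base_fast$reward_pos ||
      base_slow$reward_neg != base_fast$reward_neg)
    stop("the two modes must share emission probabilities and rewards")
  time_refinement <- as.integer(time_refinement)
  if (time_refinement < 1) stop("time_refinement must be a positive integer")
  structure(list(base_slow = base_slow, base_fast = base_fast,
                 q_sf = q_sf, q_fs = q_fs, time_refinement = time_refinement),
            class = "ext_env_params")
}

#' Default extended environment
#'
#' Slow-mode rates are the basic defaults divided by the time refinement, so
#' that per basic time bin the slow mode changes like the basic model; fast
#' rates are ten times the slow rates.  Meta switches occur with probability
#' 0.001 per extended bin.
#'
#' @param time_refinement extended bins per basic bin.
#' @return An `ext_env_params` object.
#' @export
default_ext_env_params <- function(time_refinement = 10) {
  b <- default_env_params()
  slow <- env_params(a_rn = b$a_rn / time_refinement,
                     a_nr = b$a_nr / time_refinement,
                     a_np = b$a_np / time_refinement,
                     a_pn = b$a_pn / time_refinement)
  fast <- env_params(a_rn = slow$a_rn * 10, a_nr = slow$a_nr * 10,
                     a_np = slow$a_np * 10, a_pn = slow$a_pn * 10)
  ext_env_params(slow, fast, q_sf = 0.001, q_fs = 0.001,
                 time_refinement = time_refinement)
}

#' @export
transition_matrix.ext_env_params <- function(env, ...) {
  Ps <- transition_matrix(env$base_slow)
  Pf <- transition_matrix(env$base_fast)
  M <- rbind(c(1 - env$q_sf, env$q_sf),
             c(env$q_fs, 1 - env$q_fs))
  P <- rbind(cbind(Ps * M[1, 1], Ps * M[1, 2]),
             cbind(Pf * M[2, 1], Pf * M[2, 2]))
  labels <- c(paste0(.STATES, ".s"), paste0(.STATES, ".f"))
  dimnames(P) <- list(labels, labels)
  P
}

#' @export
emission_matrix.ext_env_params <- function(env, action = c("ap", "av")) {
  action <- match.arg(action)
  E <- emission_matrix(env$base_slow, action)
  E2 <- rbind(E, E)
  rownames(E2) <- c(paste0(.STATES, ".s"), paste0(.STATES, ".f"))
  E2
}

#' @export
print.ext_env_params <- function(x, ...) {
  cat("Extended 6-state environment {r,n,p} x {slow,fast}\n")
  cat(sprintf("  meta rates: q_sf=%g q_fs=%g, refinement %d bins\n",
              x$q_sf, x$q_fs, x$time_refinement))
  cat(sprintf("  slow leaving rates a_rn=%g a_pn=%g; fast a_rn=%g a_pn=%g\n",
              x$base_slow$a_rn, x$base_slow$a_pn,
              x$base_fast$a_rn, x$base_fast$a_pn))
  invisible(x)
}

#' Marginal reward-state belief of an extended belief
#'
#' @param b a probability vector over the six extended states, ordered
#'   `(r.s, n.s, p.s, r.f, n.f, p.f)`.
#' @return Length-3 probability vector over `(r, n, p)`.
#' @export
marginal_env_belief <- function(b) {
  stats::setNames(as.numeric(b[1:3] + b[4:6]), .STATES)
}

#' Posterior probability of the slow and fast meta mode
#' @param b six-state belief vector.
#' @return Named vector `c(slow=, fast=)`.
#' @export
meta_posterior <- function(b) {
  c(slow = sum(b[1:3]), fast = sum(b[4:6]))
}
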