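# Bayesian filtering of the hidden environmental state.  The belief is the
# agent's sufficient statistic of its action-reinforcement history.
#
# Update order is correct-then-predict: the observed signal first corrects the
# belief over the state that emitted it, then one transition step predicts the
# state of the next time bin.  Under this convention an avoid step is exactly
# one multiplication by the transition matrix, and the stationary distribution
# is a fixed point of avoiding.

# one filter step given precomputed likelihood column and transition matrix
.belief_step <- function(b, lik, P) {
  post <- b * lik
  tot <- sum(post)
  if (tot <= 0)
    stop("impossible observation: zero likelihood under the current belief")
  as.numeric((post / tot) %*% P)
}

#' Bayesian belief update after one action and reinforcement signal
#'
#' Applies the filter operator `tau(b, a, y)`: the belief is multiplied by the
#' emission likelihood of the observed signal under the chosen action,
#' normalized, and pushed through one step of the environment's transition
#' matrix.  Avoiding pairs only with the neutral signal and carries no
#' information, so `belief_update(b, "av", "0", env)` equals `b %*% P`.
#'
#' @param b belief vector over the hidden states (length 3 for the basic,
#'   6 for the extended model); nonnegative, summing to 1.
#' @param action `"ap"` or `"av"`.
#' @param signal observed reinforcement signal, one of `"+"`, `"0"`, `"-"`.
#' @param env an `env_params` or `ext_env_params` object.
#' @return The updated belief vector.
#' @examples
#' env <- default_env_params()
#' b <- stationary_belief(env)
#' belief_update(b, "av", "0", env)  # fixed point
#' belief_update(b, "ap", "-", env)  # punishment shifts mass to p
#' @export
belief_update <- function(b, action = c("ap", "av"),
                          signal = c("+", "0", "-"), env) {
  action <- match.arg(action)
  signal <- match.arg(signal)
  P <- transition_matrix(env)
  if (length(b) != nrow(P)) stop("belief length does not match the state space")
  if (any(b < -1e-12) || abs(sum(b) - 1) > 1e-9)
    stop("b is not a probability vector")
  if (action == "av" && signal != "0")
    stop("avoiding always returns the neutral signal")
  E <- emission_matrix(env, action)
  stats::setNames(.belief_step(as.numeric(b), E[, signal], P), rownames(P))
}

#' Stationary belief of an environment
#' @param env an `env_params` or `ext_env_params` object.
#' @return The stationary distribution of the environment's transition matrix.
#' @export
stationary_belief <- function(env) {
  stationary_distribution(transition_matrix(env))
}

# matrix power by repeated squaring
.matpow <- function(P, k) {
  out <- diag(nrow(P))
  M <- P
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  out
}

#' Belief drift in the absence of information
#'
#' `k` consecutive avoid updates: the belief relaxes toward the stationary
#' distribution along `b %*% P^k`.  This is the model's account of
#' forgetting: no trace is erased, the posterior simply decays toward the
#' prior of a changing world.
#'
#' @param b belief vector.
#' @param k number of time bins to drift (nonnegative integer).
#' @param env an `env_params` or `ext_env_params` object.
#' @return The drifted belief vector.
#' @export
drift <- function(b, k, env) {
  if (k < 0) stop("k must be nonnegative")
  P <- transition_matrix(env)
  if (length(b) != nrow(P)) stop("belief length does not match the state space")
  if (k == 0) return(stats::setNames(as.numeric(b), rownames(P)))
  stats::setNames(as.numeric(b %*% .matpow(P, as.integer(k))), rownames(P))
}

#' Belief after a single conditioning event
#'
#' Conditioning is modeled as experiencing a defined environmental state: the
#' agent approaches and receives the signal implied by the event (`+` for
#' appetitive, `-` for aversive, `0` for neutral conditioning).
#'
#' @param event `"appetitive"`, `"aversive"` or `"neutral"`.
#' @param env environment object.
#' @param b0 belief before the event; defaults to the stationary belief.
#' @return The post-event belief.
#' @export
conditioned_belief <- function(event = c("appetitive", "aversive", "neutral"),
                               env, b0 = stationary_belief(env)) {
  event <- match.arg(event)
  signal <- switch(event, appetitive = "+", aversive = "-", neutral = "0")
  belief_update(b0, "ap", signal, env)
}
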