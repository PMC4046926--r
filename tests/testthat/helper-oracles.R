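# Independent oracles used across the test files.

# stationary distribution by brute-force power iteration
power_iter_stationary <- function(P, n = 2000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(n)) v <- as.numeric(v %*% P)
  v
}

# random irreducible basic environment
random_env <- function() {
  env_params(a_rn = runif(1, 0.01, 0.4), a_nr = runif(1, 0.01, 0.4),
             a_np = runif(1, 0.01, 0.4), a_pn = runif(1, 0.01, 0.4))
}

# random belief on the 3-simplex
random_belief <- function(n = 1) {
  x <- matrix(rexp(3 * n), n, 3)
  x / rowSums(x)
}

rlaplace <- function(n, scale) rexp(n, 1 / scale) - rexp(n, 1 / scale)

# brute-force filtering oracle: explicit sum over all hidden state paths.
# Returns the normalized distribution of the state in the bin after the last
# observation, matching the filter's correct-then-predict convention.
oracle_forward <- function(b0, acts, sigs, env) {
  P <- transition_matrix(env)
  tlen <- length(acts)
  paths <- as.matrix(expand.grid(rep(list(1:3), tlen + 1)))
  w <- b0[paths[, 1]]
  for (i in seq_len(tlen)) {
    E <- emission_matrix(env, acts[i])
    w <- w * E[cbind(paths[, i], match(sigs[i], colnames(E)))] *
      P[cbind(paths[, i], paths[, i + 1])]
  }
  J <- vapply(1:3, function(s) sum(w[paths[, tlen + 1] == s]), numeric(1))
  J / sum(J)
}

# numeric quadrature for E[max(A, B + D)], D ~ Laplace(0, s)
quad_emax <- function(A, B, s) {
  f <- function(d) pmax(A, B + d) * exp(-abs(d) / s) / (2 * s)
  stats::integrate(f, -Inf, 0, rel.tol = 1e-12)$value +
    stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
}

# Howard policy iteration for a unichain average-reward MDP.
# r: S x A reward matrix, P: list of A dense S x S transition matrices.
policy_iteration_avg <- function(r, P) {
  S <- nrow(r)
  A <- ncol(r)
  pol <- rep(1L, S)
  g <- NA_real_
  for (iter in 1:200) {
    Pp <- do.call(rbind, lapply(1:S, function(s) P[[pol[s]]][s, ]))
    rp <- r[cbind(1:S, pol)]
    # solve g * 1 + (I - Pp) h = rp with h[1] = 0
    Amat <- cbind(1, (diag(S) - Pp)[, -1])
    sol <- solve(Amat, rp)
    g <- sol[1]
    h <- c(0, sol[-1])
    q <- vapply(1:A, function(a) r[, a] + as.numeric(P[[a]] %*% h), numeric(S))
    newpol <- max.col(q, ties.method = "first")
    keep <- q[cbind(1:S, newpol)] - q[cbind(1:S, pol)] < 1e-10
    newpol[keep] <- pol[keep]
    if (all(newpol == pol)) break
    pol <- newpol
  }
  list(gain = g, policy = pol)
}

# dense expansion of the quantized belief/cost MDP produced by
# lp_quantized_mdp (cost bin redrawn i.i.d. each step)
dense_quantized_mdp <- function(mdp) {
  S <- mdp$n_states
  nb <- mdp$n_bins
  npts <- mdp$npts
  expand <- function(Pb) {
    Pbd <- as.matrix(Pb)
    # state s = belief + (bin-1)*npts ; next bin uniform
    kronecker(matrix(1 / nb, nb, nb), Pbd)
  }
  list(r = cbind(mdp$r_ap, mdp$r_av),
       P = list(expand(mdp$Pb$ap), expand(mdp$Pb$av)))
}

# enumerate all (action, signal) observation sequences of lengths 1..tmax in
# the same order as filter_tree below; pairs: 1 (ap,+), 2 (ap,0), 3 (ap,-),
# 4 (av,0)
PAIR_ACTS <- c("ap", "ap", "ap", "av")
PAIR_SIGS <- c("+", "0", "-", "0")

seq_matrices <- function(tmax) {
  out <- list()
  Q <- matrix(integer(0), 1, 0)
  for (t in seq_len(tmax)) {
    n <- nrow(Q)
    Q <- do.call(rbind, lapply(1:4, function(k) cbind(Q, k)))
    out[[t]] <- Q
  }
  out
}

# filter side: beliefs after every observation sequence, computed by the
# package's belief_update applied once per prefix-tree node, in the ordering
# of seq_matrices (child (k-1)*n + j extends parent j by pair k)
filter_tree <- function(env, tmax, b0) {
  out <- list()
  prev <- list(b0)
  for (t in seq_len(tmax)) {
    n <- length(prev)
    cur <- vector("list", 4 * n)
    for (k in 1:4) for (j in seq_len(n)) {
      cur[[(k - 1) * n + j]] <-
        belief_update(prev[[j]], PAIR_ACTS[k], PAIR_SIGS[k], env)
    }
    out[[t]] <- do.call(rbind, cur)
    prev <- cur
  }
  out
}

# oracle side: explicit path enumeration, vectorized over all sequences and
# all state paths of each length
oracle_tree <- function(env, tmax, b0) {
  P <- transition_matrix(env)
  Eap <- emission_matrix(env, "ap")
  Eav <- emission_matrix(env, "av")
  lik <- cbind(Eap[, "+"], Eap[, "0"], Eap[, "-"], Eav[, "0"])  # 3 x 4
  seqs <- seq_matrices(tmax)
  out <- list()
  for (t in seq_len(tmax)) {
    Q <- seqs[[t]]
    paths <- as.matrix(expand.grid(rep(list(1:3), t + 1)))
    np <- nrow(paths)
    transw <- b0[paths[, 1]]
    for (i in seq_len(t))
      transw <- transw * P[cbind(paths[, i], paths[, i + 1])]
    W <- matrix(1, nrow(Q), np)
    for (i in seq_len(t)) {
      Li <- t(lik[paths[, i], , drop = FALSE][, Q[, i], drop = FALSE])
      W <- W * Li
    }
    W <- W * rep(transw, each = nrow(Q))
    G <- vapply(1:3, function(s) as.numeric(paths[, t + 1] == s), numeric(np))
    J <- W %*% G
    out[[t]] <- J / rowSums(J)
  }
  out
}
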