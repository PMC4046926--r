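test_that("immediate expected reinforcement is the belief-weighted signal value", {
  env <- default_env_params()
  expect_equal(immediate_expected_reinforcement(c(1, 0, 0), env), 1)
  expect_equal(immediate_expected_reinforcement(stationary_belief(env), env),
               0, tolerance = 1e-12)  # rho = 0 by symmetry
  expect_equal(immediate_expected_reinforcement(c(0.3, 0.5, 0.2), env),
               0.3 * 1 + 0.5 * (0.005 - 0.005) + 0.2 * (-1))
})

test_that("greedy decisions follow the immediate net-reward rule with ap ties", {
  env <- default_env_params()
  g <- greedy_policy(env)
  expect_identical(decide(g, c(0.4, 0.5, 0.1), 0.2, 0.2), "ap")
  expect_identical(decide(g, c(0.1, 0.5, 0.4), 0.2, 0.2), "av")
  # equal beliefs: the cheaper action wins
  expect_identical(decide(g, c(0.2, 0.6, 0.2), 0.1, 0.3), "ap")
  expect_identical(decide(g, c(0.2, 0.6, 0.2), 0.3, 0.1), "av")
  # exact tie -> ap
  expect_identical(decide(g, c(0.2, 0.6, 0.2), 0.2, 0.2), "ap")
})

test_that("one-step provident value reduces to the closed-form cost integral", {
  env <- default_env_params()
  costs <- cost_model(0.2)
  set.seed(9)
  B <- random_belief(20)
  qap <- immediate_expected_reinforcement(B, env)
  expected <- expected_max_with_laplace_offset(qap, 0, costs) - 0.2
  expect_equal(provident_value(B, 1, env, costs), expected, tolerance = 1e-12)
  expect_error(provident_value(B[1, ], 8, env, costs), "horizon")
  expect_error(dp_config(horizon = 9), "horizon")
})

test_that("at discount zero the provident policy is exactly greedy", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  p0 <- provident_policy(env, costs, dp_config(horizon = 5, gamma = 0))
  g <- greedy_policy(env)
  set.seed(10)
  B <- random_belief(1000)
  cs <- sample_costs(costs, 1000)
  for (i in seq_len(1000)) {
    expect_identical(decide(p0, B[i, ], cs$c_ap[i], cs$c_av[i]),
                     decide(g, B[i, ], cs$c_ap[i], cs$c_av[i]))
  }
})

test_that("finite-horizon values match a Monte-Carlo cost-integration oracle", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  gamma <- 0.95
  # same recursion over signals, but the per-step expectation over the two
  # exponential costs is estimated by simulation instead of the closed form
  mc_v <- function(b, k, nmc = 2e5) {
    if (k == 0) return(0)
    P <- transition_matrix(env)
    E <- emission_matrix(env, "ap")
    qap <- immediate_expected_reinforcement(b, env)
    qav <- 0
    if (k > 1) {
      qav <- gamma * mc_v(as.numeric(b %*% P), k - 1, nmc)
      for (y in 1:3) {
        w <- b * E[, y]
        py <- sum(w)
        if (py > 0)
          qap <- qap + gamma * py * mc_v(as.numeric((w / py) %*% P), k - 1, nmc)
      }
    }
    cap <- rexp(nmc, 1 / costs$scale)
    cav <- rexp(nmc, 1 / costs$scale)
    mean(pmax(qap - cap, qav - cav))
  }
  set.seed(11)
  for (b in list(c(0.6, 0.3, 0.1), c(0.05, 0.45, 0.5), c(1, 1, 1) / 3)) {
    v_mc <- mc_v(b, 3)
    v_dp <- provident_value(b, 3, env, costs, gamma)
    expect_lt(abs(v_dp - v_mc), 3 * costs$scale / sqrt(2e5) * 3)
  }
})

test_that("decisions depend on the costs only through their difference", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  pols <- list(greedy_policy(env), provident_policy(env, costs),
               baseline_policy("immediate_forgetting", env))
  set.seed(12)
  B <- random_belief(50)
  for (pol in pols) {
    for (i in 1:50) {
      a1 <- decide(pol, B[i, ], 0.05, 0.21)
      a2 <- decide(pol, B[i, ], 0.05 + 3, 0.21 + 3)
      expect_identical(a1, a2)
    }
  }
})

test_that("decision regions are monotone in the reward belief and shrink with
           the avoid cost", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  lat <- forgetsim:::.simplex_lattice(20)
  B <- lat$points
  for (pol in list(greedy_policy(env), provident_policy(env, costs))) {
    t <- policy_threshold(pol, B)
    ap_eq <- t >= 0  # equal costs
    # walking up in b_r at fixed b_p never flips ap -> av
    for (bp in unique(B[, 3])) {
      sel <- which(abs(B[, 3] - bp) < 1e-12)
      sel <- sel[order(B[sel, 1])]
      expect_true(all(diff(ap_eq[sel]) >= 0))
    }
    # a larger avoid cost enlarges the approach region, monotonically
    n_ap <- vapply(c(0, 0.1, 0.3),
                   function(off) sum(t + off >= 0), numeric(1))
    expect_true(all(diff(n_ap) >= 0))
    expect_gt(n_ap[3], n_ap[1])
  }
})

test_that("the quantized LP recovers the closed-form rate when reinforcement
           is absent", {
  env0 <- env_params(0.04, 0.08, 0.08, 0.04, reward_pos = 0, reward_neg = 0)
  costs <- cost_model(0.2)
  lp <- lp_reward_rate_policy(env0, costs, lp_config(1 / 10, 11))
  # best achievable: always pick the cheaper action, rate -E[min] = -scale/2
  expect_lt(abs(lp$rate - (-0.1)), 0.01)
})

test_that("the LP solution matches Howard policy iteration on the same MDP", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  cfg <- lp_config(1 / 8, 5)
  lp <- lp_reward_rate_policy(env, costs, cfg)
  dm <- dense_quantized_mdp(lp_quantized_mdp(env, costs, cfg))
  ref <- policy_iteration_avg(dm$r, dm$P)
  expect_equal(lp$rate, ref$gain, tolerance = 1e-6)
  expect_gt(mean(lp$actions == ref$policy), 0.9)
})

test_that("LP decisions are deterministic functions of the cost difference", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  lp <- lp_reward_rate_policy(env, costs, lp_config(1 / 10, 11))
  b <- c(0.25, 0.35, 0.4)
  expect_identical(decide(lp, b, 0.1, 0.3), decide(lp, b, 0.1, 0.3))
  expect_identical(decide(lp, b, 0.1, 0.3), decide(lp, b, 1.1, 1.3))
  expect_identical(decide(lp, b, 0.05, 0.6), "ap")  # large c_av favours ap
})

test_that("baseline policies behave as defined", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  imf <- baseline_policy("immediate_forgetting", env)
  set.seed(13)
  cs <- sample_costs(costs, 1e5)
  acts <- decide(imf, stationary_belief(env), cs$c_ap, cs$c_av)
  expect_lt(abs(mean(acts == "ap") - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_identical(unique(decide(baseline_policy("always_ap", env),
                                 c(0, 0, 1), cs$c_ap[1:5], cs$c_av[1:5])),
                   "ap")
  expect_identical(unique(decide(baseline_policy("always_av", env),
                                 c(1, 0, 0), cs$c_ap[1:5], cs$c_av[1:5])),
                   "av")

  # forced avoidance in a reinforcement-free world just pays the avoid cost
  env0 <- env_params(0.04, 0.08, 0.08, 0.04, reward_pos = 0, reward_neg = 0)
  ev <- evaluate_total_reward(baseline_policy("always_av", env0), env0,
                              cost_model(0.2), n_steps = 400, n_runs = 30)
  expect_lt(abs(ev$mean - (-0.2 * 400)), 3 * ev$sem)
})

test_that("paired free-run comparison reports per-policy totals on shared
           streams", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  set.seed(14)
  cmp <- compare_policies(list(g = greedy_policy(env),
                               a = baseline_policy("always_av", env)),
                          env, costs, n_steps = 100, n_runs = 8)
  expect_identical(dim(attr(cmp, "totals")), c(8L, 2L))
  expect_identical(cmp$policy, c("greedy", "always_av"))
  # the avoid-everything column is pure cost, identical streams or not
  expect_true(all(attr(cmp, "totals")[, 2] < 0))
})
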