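test_that("named protocols have the published event schedules", {
  sp <- make_protocol("spaced")
  expect_equal(sp$time, c(0, 10, 20, 30, 40, 50))  # 9 waiting bins between
  expect_true(all(sp$event == "aversive"))
  ma <- make_protocol("massed")
  expect_equal(ma$time, 0:5)
  rv <- make_protocol("reversal")
  expect_equal(rv$time, 0:2)
  expect_equal(rv$event, c("aversive", "neutral", "aversive"))
  expect_identical(conditioned_response(make_protocol("single_appetitive")),
                   "ap")
  expect_identical(conditioned_response(rv), "av")
  expect_error(make_protocol("banana"))
})

test_that("forgetting curves converge to the stationary-belief fraction", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  g <- greedy_policy(env)
  set.seed(19)
  cv <- forgetting_curve(g, "single_aversive", env, costs,
                         delays = c(0, 5, 20, 80, 800), n_agents = 3000)
  f_inf <- cv$fraction_cr[cv$delay == 800]
  asym <- attr(cv, "asymptote")
  expect_lt(abs(f_inf - asym), 3 * sqrt(asym * (1 - asym) / 3000))
  # MC fractions track the exact fractions
  expect_lt(max(abs(cv$fraction_cr - cv$fraction_exact)),
            4 * max(cv$stderr) + 0.01)
  # with rho = 0 and symmetric everything the asymptote is one half
  expect_equal(asym, 0.5, tolerance = 1e-10)
})

test_that("small costs of responding saturate the fresh memory", {
  env <- default_env_params()
  g <- greedy_policy(env)
  set.seed(20)
  cv <- forgetting_curve(g, "single_aversive", env, cost_model(0.02),
                         delays = c(0, 2), n_agents = 500)
  expect_gt(cv$fraction_cr[1], 0.98)
})

test_that("slower environments are forgotten more slowly and larger cost
           variance flattens the curve", {
  delays <- default_delays(800, 17)
  costs <- cost_model(0.1)
  env_fast <- default_env_params()
  env_slow <- env_params(0.01, 0.02, 0.02, 0.01)  # same structure, 4x slower
  cv_f <- forgetting_curve(greedy_policy(env_fast), "single_aversive",
                           env_fast, costs, delays, n_agents = 10)
  cv_s <- forgetting_curve(greedy_policy(env_slow), "single_aversive",
                           env_slow, costs, delays, n_agents = 10)
  expect_true(all(cv_s$fraction_exact >= cv_f$fraction_exact - 1e-9))
  expect_gt(half_gap_delay(cv_s), half_gap_delay(cv_f))

  # larger cost scale pulls every point toward one half
  cv_big <- forgetting_curve(greedy_policy(env_fast), "single_aversive",
                             env_fast, cost_model(0.4), delays, n_agents = 10)
  expect_true(all(abs(cv_big$fraction_exact - 0.5) <=
                    abs(cv_f$fraction_exact - 0.5) + 1e-9))
})

test_that("positive average reward lifts the appetitive asymptote", {
  costs <- cost_model(0.1)
  env0 <- reparam_to_rates(p_n = 0.5, rho = 0, timescale_rate = 0.04)
  env1 <- reparam_to_rates(p_n = 0.5, rho = 0.15, timescale_rate = 0.04)
  g0 <- greedy_policy(env0); g1 <- greedy_policy(env1)
  cv0 <- forgetting_curve(g0, "single_appetitive", env0, costs,
                          delays = c(0, 500), n_agents = 10)
  cv1 <- forgetting_curve(g1, "single_appetitive", env1, costs,
                          delays = c(0, 500), n_agents = 10)
  expect_gt(attr(cv1, "asymptote"), attr(cv0, "asymptote"))
  expect_gt(attr(cv1, "asymptote"), 0.5)
  expect_equal(attr(cv0, "asymptote"), 0.5, tolerance = 1e-10)
})

test_that("the no-forgetting baseline never forgets", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  nf <- baseline_policy("no_forgetting", env)
  set.seed(21)
  cv <- forgetting_curve(nf, "single_aversive", env, costs,
                         delays = c(0, 10, 100), n_agents = 400)
  expect_equal(cv$fraction_exact, rep(cv$fraction_exact[1], 3))
  expect_true(is.na(half_gap_delay(cv)) || half_gap_delay(cv) == 0)
})

test_that("provident forgetting is asymmetric, greedy forgetting is not", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  set.seed(22)
  asy <- asymmetry_experiment(env, costs, n_agents = 300)
  expect_lt(asy$half_gap["aversive"], asy$half_gap["appetitive"])
  gre <- asymmetry_experiment(env, costs, policy = greedy_policy(env),
                              n_agents = 50)
  expect_equal(unname(gre$half_gap["aversive"]),
               unname(gre$half_gap["appetitive"]), tolerance = 1e-8)
  expect_error(asymmetry_experiment(env_params(0.1, 0.05, 0.05, 0.2), costs),
               "symmetric")
})

test_that("the extended model orders spaced, massed and reversal correctly", {
  ex <- default_ext_env_params()
  costs <- cost_model(0.1)
  set.seed(23)
  res <- extended_forgetting(ex, costs, delays = default_delays(200, 15),
                             n_agents = 500)
  sp <- res$slow_posterior
  expect_gt(sp["spaced"], sp["massed"])    # spacing argues for a slow world
  expect_lt(sp["reversal"], 0.5)           # reversal argues for a fast one
  expect_gt(res$half_gap["spaced"], res$half_gap["massed"])
  expect_gt(res$half_gap["massed"], res$half_gap["reversal"])
})

test_that("retest groups express the conditioned response at equal rates", {
  env <- default_env_params()
  costs <- cost_model(0.1)
  g <- greedy_policy(env)
  # a delay where the conditioned fraction is moderate, so both retest
  # groups are well populated and the binomial s.e. is meaningful
  b <- drift(conditioned_belief("aversive", env), 50, env)
  set.seed(25)
  rt <- retest_experiment(g, b, costs, n_agents = 4000, conditioned = "av")
  gap <- abs(diff(rt$retest_fraction))
  expect_lt(gap, 3 * sqrt(sum(rt$retest_se^2)))
  # and both retest fractions agree with the first-test fraction
  expect_lt(abs(rt$retest_fraction[1] - rt$first_fraction),
            4 * sqrt(rt$retest_se[1]^2 + 0.25 / rt$group_sizes[1]))
})

test_that("the command line interface writes deterministic artifacts", {
  out1 <- tempfile("cli1"); out2 <- tempfile("cli2")
  args <- c("curve", "--seed", "11", "--n-agents", "10",
            "--delays", "0,5,20")
  expect_identical(run_cli(c(args, "--out", out1)), 0L)
  expect_identical(run_cli(c(args, "--out", out2)), 0L)
  f1 <- file.path(out1, "curve.csv"); f2 <- file.path(out2, "curve.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  cv <- read.csv(f1)
  expect_identical(nrow(cv), 3L)
  expect_identical(names(cv), c("delay", "fraction_cr", "stderr", "n_agents"))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(man$command, "curve")
  expect_equal(man$seed, 11)

  # a different seed changes the sampled fractions
  out3 <- tempfile("cli3")
  run_cli(c("curve", "--seed", "12", "--n-agents", "10",
            "--delays", "0,5,20", "--out", out3))
  expect_false(identical(readLines(f1),
                         readLines(file.path(out3, "curve.csv"))))

  # invalid config is rejected with a nonzero status
  bad <- tempfile(fileext = ".yaml")
  writeLines("schema: something-else/9", bad)
  expect_gt(suppressMessages(run_cli(c("curve", "--config", bad,
                                       "--out", tempfile()))), 0L)
})

test_that("compare-policies command ranks the policies in one table", {
  out <- tempfile("cmp")
  cfgf <- tempfile(fileext = ".yaml")
  cfg <- default_config()
  cfg$experiment$free_run_steps <- 60
  cfg$experiment$free_run_n <- 6
  yaml::write_yaml(cfg, cfgf)
  expect_identical(run_cli(c("compare-policies", "--seed", "3",
                             "--config", cfgf, "--out", out)), 0L)
  tab <- read.csv(file.path(out, "policy_comparison.csv"))
  expect_identical(tab$policy[1], "greedy")
  expect_identical(tab$policy[2], "provident_K5_gamma0.95")
  expect_identical(nrow(tab), 4L)
})
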