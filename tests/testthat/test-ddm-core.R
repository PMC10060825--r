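test_that("choice pairs validate their invariants and derive differences", {
  p <- anchor_pair()
  expect_equal(p$money_diff, 21)
  expect_equal(p$delay_diff, 30)
  expect_error(choice_pairs(38, 0, 17, 30), "exceed")
  expect_error(choice_pairs(17, 30, 38, 30), "delay_ll")
  expect_error(choice_pairs(-1, 0, 38, 30), "amount_ss")
})

test_that("drift rate is the linear attribute combination", {
  p <- ddm_params(dc = 0, wm = 0.047, wd = -0.009)
  expect_equal(drift_rate(p, anchor_pair()), 0.047 * 21 - 0.009 * 30)
  expect_equal(drift_rate(p, anchor_pair()), 0.717)
  expect_equal(drift_rate(ddm_params(dc = 0, wm = 0, wd = 0), anchor_pair()), 0)
  expect_equal(drift_rate(ddm_params(dc = 0.1, wm = 0, wd = 0), anchor_pair()), 0.1)
  # sign-free: strongly delay-weighted pairs give negative drift
  expect_lt(drift_rate(ddm_params(dc = 0, wm = 0.01, wd = -0.03), anchor_pair()), 0)
})

test_that("closed-form choice probability matches its known values and limits", {
  expect_equal(choice_probability(0, 2, 0.5), 0.5)
  expect_equal(choice_probability(0, 2, 0.3), 0.3)
  expect_equal(choice_probability(1, 2, 0.5), (1 - exp(-2)) / (1 - exp(-4)),
               tolerance = 1e-12)
  expect_equal(choice_probability(1, 2, 0.5), 0.8808, tolerance = 1e-4)
  expect_equal(choice_probability(0.717, 2, 0.5), 0.8075, tolerance = 1e-4)
  # overflow guards return bounded limits
  expect_equal(choice_probability(1e4, 5, 0.5), 1)
  expect_equal(choice_probability(-1e4, 5, 0.5), 0)
  expect_true(all(choice_probability(c(-3, 0, 3), 1.5, 0.4) > 0))
})

test_that("choice probability is strictly increasing in drift and start point", {
  v_grid <- seq(-2, 2, length.out = 21)
  for (a in c(0.5, 1.5, 3)) {
    p <- choice_probability(v_grid, a, 0.4)
    expect_true(all(diff(p) > 0))
  }
  z_grid <- seq(0.1, 0.9, length.out = 17)
  for (v in c(-1, 0.3, 2)) {
    p <- vapply(z_grid, function(z) choice_probability(v, 1.8, z), 0)
    expect_true(all(diff(p) > 0))
  }
})

test_that("first-passage densities are symmetric, normalized and consistent", {
  t <- seq(0.05, 3, by = 0.05)
  # symmetry at zero drift, central start
  expect_equal(wfpt_density(t, 0, 1.5, 0.5, boundary = "upper"),
               wfpt_density(t, 0, 1.5, 0.5, boundary = "lower"))
  # normalization and mass split on a parameter grid
  for (a in c(0.5, 1.5, 3)) for (v in c(-2, 0.5, 2)) for (z in c(0.2, 0.8)) {
    up <- integrate(function(t) wfpt_density(t, v, a, z, boundary = "upper"),
                    0, Inf)$value
    lo <- integrate(function(t) wfpt_density(t, v, a, z, boundary = "lower"),
                    0, Inf)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, choice_probability(v, a, z), tolerance = 1e-4)
  }
  expect_error(wfpt_density(-0.1, 0, 1.5, 0.5), "> 0")
})

test_that("small-time and large-time series agree in the interior", {
  for (t in c(0.2, 0.4, 0.8, 1.5)) {
    small <- wfpt_density(t, 0.5, 1.5, 0.5, method = "small")
    large <- wfpt_density(t, 0.5, 1.5, 0.5, method = "large")
    expect_equal(small, large, tolerance = 1e-8)
  }
})

test_that("diffusion scale is non-identifiable: consistent rescaling is a no-op", {
  for (v in c(-1, 0.7)) {
    expect_equal(choice_probability(v, 2, 0.4, s = 1),
                 choice_probability(v / 10, 2 / 10, 0.4, s = 0.1),
                 tolerance = 1e-12)
    expect_equal(wfpt_density(0.6, v, 2, 0.4, s = 1),
                 wfpt_density(0.6, v / 10, 2 / 10, 0.4, s = 0.1),
                 tolerance = 1e-10)
  }
})

test_that("simulated trials respect the non-decision floor and drift dominance", {
  set.seed(11)
  p <- ddm_params(z = 0.5, a = 1, t0 = 0.3, dc = 10)
  sim <- simulate_trials(p, anchor_pair()[rep(1, 1e4), ])
  expect_true(all(sim$rt >= 0.3))
  expect_gte(mean(sim$choice == "LL"), 0.99)
})

test_that("simulator choice fractions match the closed form", {
  set.seed(12)
  n <- 2e4
  for (case in list(c(v = 1, a = 2, z = 0.5), c(v = -0.5, a = 1.2, z = 0.3))) {
    p <- ddm_params(z = case["z"], a = case["a"], t0 = 0.2, dc = case["v"])
    sim <- simulate_trials(p, anchor_pair()[rep(1, n), ])
    p_true <- choice_probability(case["v"], case["a"], case["z"])
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(sim$choice == "LL") - p_true), 3 * se)
  }
})

test_that("extreme parameters trigger the censoring guard", {
  set.seed(13)
  p <- ddm_params(z = 0.5, a = 4.9, t0 = 0.2, dc = 0, s = 0.05)
  sim <- simulate_trials(p, anchor_pair()[rep(1, 5), ], cap = 0.5)
  expect_true(all(sim$censored))
  expect_true(all(is.na(sim$choice)))
})

test_that("negative log-likelihood is additive and anchored to the density", {
  p <- ddm_params(z = 0.5, a = 1.5, t0 = 0.25, dc = 0, wm = 0.03, wd = -0.01)
  one <- sim_participant(p, n_trials = 1, seed = 21)
  v <- drift_rate(p, one)
  dens <- wfpt_density(one$rt - 0.25, v, 1.5, 0.5,
                       boundary = if (one$choice == "LL") "upper" else "lower")
  expect_equal(ddm_negloglik(p, one), -log(dens), tolerance = 1e-10)
  many <- sim_participant(p, n_trials = 50, seed = 22)
  expect_equal(ddm_negloglik(p, rbind(many, many)), 2 * ddm_negloglik(p, many))
  expect_error(ddm_negloglik(p, many[0, ]), "non-empty")
})

test_that("the likelihood prefers the generating parameters to a perturbed boundary", {
  truth <- ddm_params(z = 0.5, a = 1.5, t0 = 0.3, dc = 0.1, wm = 0.05, wd = -0.01)
  wrong <- ddm_params(z = 0.5, a = 1.5 * 1.5, t0 = 0.3, dc = 0.1,
                      wm = 0.05, wd = -0.01)
  wins <- 0
  for (r in 1:20) {
    tr <- sim_participant(truth, n_trials = 200, seed = 100 + r)
    if (ddm_negloglik(truth, tr) <= ddm_negloglik(wrong, tr)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("trial CSV round-trips through the documented schema", {
  p <- ddm_params(z = 0.5, a = 1.5, t0 = 0.3, dc = 0.5)
  tr <- sim_participant(p, n_trials = 20, seed = 31)
  tr$participant_id <- "P001"
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(back$choice, tr$choice)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  expect_equal(back$money_diff, tr$money_diff)
})
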