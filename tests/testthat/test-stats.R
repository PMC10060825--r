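test_that("two-group F from summaries matches hand arithmetic and handles ties", {
  # (1, 1, 10) vs (2, 1, 10): F = t^2 with t = 1 / sqrt(2/10)
  an <- oneway_f_from_groups(group_stats(mean = 1, sd = 1, n = 10),
                             group_stats(mean = 2, sd = 1, n = 10))
  expect_equal(an$f, 5)
  expect_equal(an$df2, 18)
  same <- group_stats(mean = 3, sd = 1.2, n = 15)
  an0 <- oneway_f_from_groups(same, same)
  expect_equal(an0$f, 0)
  expect_equal(an0$eta_sq, 0)
  # zero pooled variance with unequal means -> infinite-F flag
  inf <- oneway_f_from_groups(group_stats(mean = 1, sd = 0, n = 5),
                              group_stats(mean = 2, sd = 0, n = 5))
  expect_true(inf$infinite_f)
  expect_identical(inf$f, Inf)
})

test_that("summary-based F agrees with raw-data oracles to numerical precision", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    x1 <- rnorm(n1, sample(0:2, 1)); x2 <- rnorm(n2)
    an <- oneway_f_from_groups(group_stats(x1), group_stats(x2))
    bf <- brute_force_f(x1, x2)
    expect_equal(an$f, bf$f, tolerance = 1e-10)
    expect_equal(an$p, bf$p, tolerance = 1e-10)
    expect_equal(an$eta_sq, bf$eta_sq, tolerance = 1e-10)
    # and with the built-in ANOVA machinery
    dat <- data.frame(y = c(x1, x2), g = rep(c("a", "b"), c(n1, n2)))
    ref <- anova(lm(y ~ g, dat))
    expect_equal(an$f, ref$`F value`[1], tolerance = 1e-10)
  }
})

test_that("eta squared follows F and the design degrees of freedom", {
  expect_equal(round(eta_squared(35.949, 1, 70), 3), 0.339)
  expect_equal(round(eta_squared(14.327, 1, 111), 3), 0.114)
  expect_equal(eta_squared(0, 1, 50), 0)
  # identity with the two-group one-way decomposition
  an <- oneway_f_from_groups(group_stats(mean = 0, sd = 1, n = 12),
                             group_stats(mean = 1, sd = 1, n = 12))
  expect_equal(an$eta_sq, an$f / (an$f + an$df2))
})

test_that("covariate adjustment reduces to the one-way F and flags aliasing", {
  set.seed(102)
  g <- rep(c("control", "separated"), each = 20)
  y <- rnorm(40) + 0.8 * (g == "separated")
  plain <- oneway_f_from_groups(group_stats(y[g == "separated"]),
                                group_stats(y[g == "control"]))
  adj0 <- ancova_group_effect(y, g)
  expect_equal(adj0$f, plain$f, tolerance = 1e-10)
  expect_equal(adj0$p, plain$p, tolerance = 1e-10)
  covs <- data.frame(age = rnorm(40), income = rnorm(40))
  adj <- ancova_group_effect(y, g, covs)
  expect_equal(adj$df2, 36)
  expect_lt(abs(adj$f - plain$f) / plain$f, 0.5) # noise covariates: same story
  # covariate identical to the group label is aliased
  expect_error(ancova_group_effect(y, g, data.frame(dup = as.integer(g == "separated"))),
               "alias")
})

test_that("pearson correlation matches hand computation and null behaviour", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 2))$r, sqrt(3) / 2,
               tolerance = 1e-12)
  set.seed(103)
  null <- pearson_r(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("Cronbach's alpha is 1 for clones, ~0 for noise, negative when incoherent", {
  set.seed(104)
  base <- rnorm(100)
  clones <- cbind(base, base, base)
  expect_equal(cronbach_alpha(clones), 1)
  noise <- matrix(rnorm(500 * 10), 500, 10)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)
  anti <- cbind(base, -base + rnorm(100, sd = 0.1))
  expect_lt(cronbach_alpha(anti), 0)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total")
})

test_that("median split assigns ties to the low group", {
  sp <- median_split(c(1, 2, 3, 4))
  expect_equal(sp$median, 2.5)
  expect_equal(as.character(sp$labels), c("low", "low", "high", "high"))
  tied <- median_split(c(30, 33, 33, 33, 40, 45))
  expect_equal(tied$median, 33)
  expect_equal(sum(tied$labels == "low"), 4)
  expect_warning(deg <- median_split(rep(5, 4)), "empty group")
  expect_true(deg$degenerate)
})

test_that("simple mediation recovers configured paths and is seed-stable", {
  set.seed(105)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  y <- 0.4 * m + sqrt(1 - 0.16) * rnorm(n)
  fit <- mediation_simple(x, m, y, n_boot = 500, seed = 3)
  expect_lt(abs(fit$paths["a"] - 0.5), 0.15)
  expect_lt(abs(fit$paths["b"] - 0.4), 0.15)
  expect_lt(abs(fit$indirect - 0.2), 0.12)
  expect_true(fit$ci_low < fit$indirect & fit$indirect < fit$ci_high)
  refit <- mediation_simple(x, m, y, n_boot = 500, seed = 3)
  expect_identical(fit$ci_low, refit$ci_low)
  expect_identical(fit$boot_se, refit$boot_se)
  # null b path: CI covers zero
  y0 <- 0.3 * x + rnorm(n)
  null_fit <- mediation_simple(x, m, y0, n_boot = 500, seed = 4)
  expect_true(null_fit$ci_low < 0 & null_fit$ci_high > 0)
  expect_error(mediation_simple(x[1:5], m[1:5], y[1:5]), "at least 10")
  expect_error(mediation_simple(x, x, y), "collinear")
})

test_that("serial mediation reports all indirect paths with a zero-path guard", {
  gen <- generate_mediation_truth(n = 300, a1 = 0.6, d21 = 0.5, b2 = 0.4,
                                  seed = 11)
  d <- gen$data
  fit <- mediation_serial(d$x, d$m1, d$m2, d$y, n_boot = 500, seed = 5)
  expect_equal(nrow(fit$indirect_table), 3)
  expect_lt(abs(fit$indirect - 0.12), 0.06)
  expect_lt(abs(fit$paths["a1"] - 0.6), 0.12)
  expect_lt(abs(fit$paths["d21"] - 0.5), 0.12)
  # a zero path in the chain nulls the serial product
  gen0 <- generate_mediation_truth(n = 300, a1 = 0, d21 = 0.5, b2 = 0.4,
                                   seed = 12)
  fit0 <- mediation_serial(gen0$data$x, gen0$data$m1, gen0$data$m2,
                           gen0$data$y, n_boot = 300, seed = 6)
  expect_lt(abs(fit0$indirect), 0.05)
})

test_that("parallel mediation isolates the mediator that carries the path", {
  set.seed(106)
  n <- 250
  x <- rnorm(n)
  m1 <- 0.6 * x + 0.8 * rnorm(n)       # true mediator
  m2 <- 0.5 * x + 0.87 * rnorm(n)      # correlated with x, no path to y
  y <- 0.5 * m1 + 0.87 * rnorm(n)
  fit <- mediation_parallel(x, cbind(med = m1, dud = m2), y,
                            n_boot = 500, seed = 7)
  tab <- fit$indirect_table
  expect_gt(tab$ci_low[tab$path == "x->med->y"], 0)
  expect_true(tab$ci_low[tab$path == "x->dud->y"] < 0 &
                tab$ci_high[tab$path == "x->dud->y"] > 0)
})

test_that("bootstrap confidence intervals tighten like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    gen <- generate_mediation_truth(n = n, a1 = 0.5, d21 = 0, b2 = 0,
                                    b1 = 0.4, seed = 21)
    fit <- mediation_simple(gen$data$x, gen$data$m1, gen$data$y,
                            n_boot = 600, seed = 8)
    fit$ci_high - fit$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
  ratios <- widths[-3] / widths[-1]
  expect_true(all(ratios > 1.3 & ratios < 3.1))
})

test_that("an x-independent mediator leaves the indirect effect centred at zero", {
  set.seed(107)
  n <- 150
  x <- rnorm(n)
  m <- rnorm(n)                       # independent of x
  y <- 0.5 * x + 0.5 * m + rnorm(n)
  fit <- mediation_simple(x, m, y, n_boot = 800, seed = 9)
  expect_lt(abs(fit$indirect), 2 * fit$boot_se)
})
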