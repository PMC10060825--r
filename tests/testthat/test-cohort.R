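tiny_config <- function(...) {
  cohort_config(n_per_group = 6, n_trials = 12, ...)
}

test_that("the default choice menu spans the task scale and includes the anchor", {
  menu <- generate_choice_menu()
  expect_equal(nrow(menu), 80)
  expect_true(any(menu$amount_ss == 17 & menu$amount_ll == 38 &
                    menu$delay_ll == 30))
  # every pair satisfies the invariants (constructor re-validates)
  expect_silent(itcddm:::validate_choice_pairs(menu))
  expect_true(all(menu$money_diff > 0 & menu$delay_diff > 0))
})

test_that("config validation rejects malformed and infeasible settings", {
  expect_error(cohort_config(bogus_field = 1), "unknown config")
  expect_error(cohort_config(sas = list(r_state = list(separated = 1.2))),
               "correlations")
  # r / sqrt(alpha) > 1 is not a correlation at the latent level
  expect_error(cohort_config(sas = list(alpha = 0.15,
                                        r_state = list(separated = 0.6))),
               "infeasible")
})

test_that("cohort generation is byte-identical under a fixed seed", {
  c1 <- generate_cohort(tiny_config(), seed = 77)
  c2 <- generate_cohort(tiny_config(), seed = 77)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(tiny_config(), seed = 78)
  expect_false(identical(c1$participants, c2$participants) &&
                 identical(c1$trials, c3$trials))
  dir <- withr::local_tempdir()
  write_cohort_csv(c1, dir)
  expect_true(all(file.exists(file.path(dir, c("participants.csv",
                                               "trials.csv", "truth.csv")))))
})

test_that("generated records respect every downstream type invariant", {
  cohort <- generate_cohort(tiny_config(), seed = 5)
  pp <- cohort$participants
  expect_true(all(pp$sas_total >= 11 & pp$sas_total <= 55))
  expect_true(all(pp$restaurant_wait >= 5 & pp$restaurant_wait <= 60))
  expect_true(all(pp$movie_timing >= 1 & pp$movie_timing <= 100))
  expect_true(all(pp$gift_compensation >= 1 & pp$gift_compensation <= 50))
  expect_true(all(cohort$truth$a > 0))
  expect_true(all(cohort$truth$z > 0 & cohort$truth$z < 1))
  ok <- !cohort$trials$censored
  expect_true(all(cohort$trials$rt[ok] > 0))
  expect_true(all(cohort$trials$choice[ok] %in% c("SS", "LL")))
  expect_true(all(pp$n_impulsive >= 0 & pp$n_impulsive <= 12))
  expect_true(all(cohort$sas_items >= 1 & cohort$sas_items <= 5))
})

test_that("cohort statistics calibrate to the configured group structure", {
  cfg <- cohort_config(n_per_group = 36, n_trials = 4)
  anx_sep <- anx_ctl <- wm_diff <- r_sep <- numeric(4)
  for (i in 1:4) {
    cohort <- generate_cohort(cfg, seed = 300 + i)
    pp <- cohort$participants
    sep <- pp$group == "separated"
    anx_sep[i] <- mean(pp$stai_state[sep])
    anx_ctl[i] <- mean(pp$stai_state[!sep])
    wm_diff[i] <- mean(cohort$truth$wm[!sep]) - mean(cohort$truth$wm[sep])
    r_sep[i] <- pearson_r(pp$sas_total[sep], pp$stai_state[sep])$r
  }
  # group means within ~3 standard errors of the configured targets
  expect_lt(abs(mean(anx_sep) - 37.50), 3 * 7.25 / sqrt(36 * 4))
  expect_lt(abs(mean(anx_ctl) - 29.11), 3 * 4.23 / sqrt(36 * 4))
  expect_gt(mean(wm_diff), 0)            # control carries the larger weight
  expect_gt(mean(r_sep), 0.15)           # separation-only correlation present
})

test_that("the SAS item generator hits its reliability target", {
  cfg <- cohort_config(n_per_group = 100, n_trials = 1)
  cohort <- generate_cohort(cfg, seed = 9)
  expect_equal(dim(cohort$sas_items), c(200, 11))
  alpha <- cronbach_alpha(cohort$sas_items)
  expect_gt(alpha, 0.72)
  expect_lt(alpha, 0.88)
})

test_that("titration cohorts place the switch at the hyperbolic present value", {
  # zero response noise, k = 1/60: present value 100, switch inside [95, 105]
  cfg <- cohort_config(titration = list(n = 5, k_meanlog = log(1 / 60),
                                        k_sdlog = 1e-12, temperature = 1e-9))
  cohort <- generate_titration_cohort(cfg, seed = 1)
  expect_true(all(abs(cohort$participants$indifference_point - 100) <= 5))
  # present value above the whole grid: everything delayed, censored high
  cfg0 <- cohort_config(titration = list(n = 4, delayed_amount = 400,
                                         k_meanlog = log(1e-8),
                                         k_sdlog = 1e-12, temperature = 1e-9))
  c0 <- generate_titration_cohort(cfg0, seed = 2)
  expect_true(all(c0$participants$censored == "high"))
  expect_true(all(c0$participants$indifference_point == 205))
})

test_that("the default titration cohort carries no SAS-impulsivity association", {
  sig <- vapply(1:6, function(i) {
    cohort <- generate_titration_cohort(cohort_config(), seed = 400 + i)
    pearson_r(cohort$participants$sas_total,
              cohort$participants$indifference_point)$p < 0.05
  }, TRUE)
  expect_lte(sum(sig), 1)
})

test_that("survey cohorts carry the extended-self pathway and stay in range", {
  cohort <- generate_survey_cohort(cohort_config(), seed = 31)
  pp <- cohort$participants
  expect_equal(nrow(pp), 113)
  expect_true(all(pp$extended_self >= 1 & pp$extended_self <= 7))
  expect_true(all(pp$anxiety >= 1 & pp$anxiety <= 5))
  expect_true(all(pp$fomo_mean >= 1 & pp$fomo_mean <= 5))
  # addiction loads on the mediators and anxiety
  expect_gt(pearson_r(pp$sas_total, pp$extended_self)$r, 0.2)
  expect_gt(pearson_r(pp$sas_total, pp$anxiety)$r, 0.1)
  expect_identical(pp$group,
                   median_split(pp$sas_total)$labels)
})

test_that("mediation truth generation stores exactly the configured products", {
  gen <- generate_mediation_truth(n = 72, a1 = 0.6, d21 = 0.5, b2 = 0.4,
                                  seed = 3)
  expect_equal(gen$truth$ind_serial, 0.12)
  gen0 <- generate_mediation_truth(n = 72, a1 = 0, d21 = 0, b2 = 0, seed = 3)
  expect_equal(gen0$truth$ind_serial, 0)
  expect_equal(gen0$truth$ind_m1, 0)
  # unit-variance construction: realized variances close to 1
  v <- vapply(generate_mediation_truth(n = 5000, seed = 4)$data, var, 0)
  expect_true(all(abs(v[c("m1", "m2", "y")] - 1) < 0.1))
})

test_that("config files round-trip through structured text", {
  cfg <- tiny_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
})
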