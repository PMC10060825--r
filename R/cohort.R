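#' Configuration of the synthetic smartphone-separation cohorts
#'
#' Bundles every tunable of the cohort generators with defaults taken from
#' the experimental conditions the package emulates: two groups of 36
#' participants, a separation-group drop in the money weight (0.047 vs
#' 0.023, SDs 0.029/0.026) with essentially unchanged delay weight, higher
#' state anxiety under separation (37.50/7.25 vs 29.11/4.23) with no trait
#' shift, an SAS (11-55) built from 11 parallel items at target alpha 0.80
#' that correlates 0.414 with state anxiety in the separation group only,
#' scenario responses with the corresponding group shifts, a within-group
#' anxiety-to-money-weight coupling for the mediation chain, a titration
#' cohort (X = 10, 20, ..., 200 now vs 200 in 60 days) with
#' lognormal discount rates unrelated to the SAS (a null), and a
#' survey-shaped cohort where the extended self carries the addiction to
#' anxiety path.
#'
#' Overrides are supplied as named arguments and merged recursively, e.g.
#' `cohort_config(n_per_group = 10, ddm = list(separated = list(wm =
#' c(0.047, 0.029))))`.
#'
#' @param ... Named overrides of the defaults.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(...) {
  defaults <- list(
    n_per_group = 36,
    n_trials = 80,
    menu = list(amount_ss = c(13, 17, 21, 25),
                amount_ll = c(31, 38, 45, 52),
                delay_ll = c(15, 30, 45, 60, 90)),
    ddm = list(
      control = list(z = c(0.5, 0.05), a = c(1.6, 0.3), t0 = c(0.35, 0.08),
                     dc = c(0, 0.1), wm = c(0.047, 0.029), wd = c(-0.009, 0.002)),
      separated = list(z = c(0.5, 0.05), a = c(1.6, 0.3), t0 = c(0.35, 0.08),
                       dc = c(0, 0.1), wm = c(0.023, 0.026), wd = c(-0.010, 0.002))
    ),
    anxiety = list(
      state = list(control = c(29.11, 4.23), separated = c(37.50, 7.25),
                   range = c(20, 80)),
      trait = list(control = c(31.78, 3.78), separated = c(32.83, 4.35),
                   range = c(20, 80))
    ),
    sas = list(n_items = 11, alpha = 0.80, item_range = c(1, 5),
               total_range = c(11, 55),
               control = c(34.86, 2.75), separated = c(33.58, 2.83),
               r_state = list(control = 0, separated = 0.414)),
    scenarios = list(
      restaurant = list(control = c(29.89, 14.41), separated = c(24.06, 12.59),
                        range = c(5, 60)),
      movie = list(control = c(87.75, 17.72), separated = c(80.72, 29.36),
                   range = c(1, 100)),
      gift = list(control = c(26.3, 13.4), separated = c(26.3, 13.4),
                  range = c(1, 50))
    ),
    # standardized within-group coupling of state anxiety to the money weight
    mediation = list(b_anxiety_wm = -0.5),
    titration = list(n = 185, grid = seq(10, 200, by = 10),
                     delayed_amount = 200, delay = 60,
                     k_meanlog = log(0.0082), k_sdlog = 0.6,
                     temperature = 8,
                     sas = c(33.8, 5.8)),
    survey = list(n = 113, sas = c(33.5, 5.5),
                  extended_self = list(mean_sd = c(4.3, 1.2), range = c(1, 7),
                                       path = 0.45),
                  fomo = list(mean_sd = c(2.95, 0.60), range = c(1, 5),
                              path = 0.40),
                  social_threat = list(mean_sd = c(3.0, 0.8), range = c(1, 5),
                                       path = 0.30),
                  anxiety = list(mean_sd = c(3.1, 1.1), range = c(1, 5),
                                 b_extended_self = 0.40, b_fomo = 0,
                                 b_social_threat = 0, c_direct = 0.12))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1, cfg$n_trials >= 1)
  sds <- c(cfg$ddm$control$wm[2], cfg$ddm$separated$wm[2],
           cfg$anxiety$state$control[2], cfg$anxiety$state$separated[2],
           cfg$sas$control[2], cfg$sas$separated[2])
  if (any(sds < 0)) stop("all SDs must be >= 0")
  rs <- c(cfg$sas$r_state$control, cfg$sas$r_state$separated)
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]")
  a <- cfg$sas$alpha
  if (any(abs(rs) / sqrt(a) > 1)) {
    stop("infeasible correlation: |r| / sqrt(alpha) exceeds 1 ",
         "(the latent correlation implied by the target alpha is not a ",
         "correlation); adjust r_state or alpha")
  }
  invisible(cfg)
}

#' Read or write a cohort configuration as structured text (YAML)
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns the `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

# truncated-normal draws by resampling (no boundary spikes)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation region has negligible mass")
  }
  out
}

#' Deterministic menu of intertemporal choice pairs
#'
#' Crosses the configured immediate amounts, delayed amounts and delays
#' (default 4 x 4 x 5 = 80 pairs, spanning the scale of the "17 today or
#' 38 in 30 days" anchor pair, which the default menu contains).
#'
#' @param config A [cohort_config()].
#' @return A `choice_pairs` tibble.
#' @export
generate_choice_menu <- function(config = cohort_config()) {
  g <- expand.grid(amount_ss = config$menu$amount_ss,
                   amount_ll = config$menu$amount_ll,
                   delay_ll = config$menu$delay_ll)
  choice_pairs(amount_ss = g$amount_ss, delay_ss = 0,
               amount_ll = g$amount_ll, delay_ll = g$delay_ll)
}

# one group's participant-level latent draws + trials
generate_group <- function(config, group, ids, menu, dt) {
  n <- length(ids)
  dp <- config$ddm[[group]]
  z <- rnorm_trunc(n, dp$z[1], dp$z[2], 0.05, 0.95)
  a <- rnorm_trunc(n, dp$a[1], dp$a[2], 0.1, 5)
  t0 <- rnorm_trunc(n, dp$t0[1], dp$t0[2], 0.05, 2)
  dc <- rnorm(n, dp$dc[1], dp$dc[2])

  # SAS total + state anxiety: latent true score correlated with anxiety at
  # rho = r_target / sqrt(alpha) so the observed total correlates at r_target
  sas_cfg <- config$sas
  k <- sas_cfg$n_items
  alpha <- sas_cfg$alpha
  M <- sas_cfg[[group]][1]
  S <- sas_cfg[[group]][2]
  sigma_T <- sqrt(alpha) * S / k
  sigma_e <- sqrt((1 - alpha) * S^2 / k)
  rho <- sas_cfg$r_state[[group]] / sqrt(alpha)
  anx_cfg <- config$anxiety$state[[group]]
  anx_rng <- config$anxiety$state$range
  items <- matrix(NA_real_, n, k)
  stai_state <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- rnorm(1)
      u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(1)
      anx <- anx_cfg[1] + anx_cfg[2] * u1
      row <- M / k + sigma_T * u2 + rnorm(k, 0, sigma_e)
      tot <- sum(row)
      if (anx >= anx_rng[1] && anx <= anx_rng[2] &&
          all(row >= sas_cfg$item_range[1] & row <= sas_cfg$item_range[2]) &&
          tot >= sas_cfg$total_range[1] && tot <= sas_cfg$total_range[2]) {
        items[i, ] <- row
        stai_state[i] <- anx
        break
      }
    }
  }
  sas_total <- rowSums(items)
  trait_cfg <- config$anxiety$trait[[group]]
  stai_trait <- rnorm_trunc(n, trait_cfg[1], trait_cfg[2],
                            config$anxiety$trait$range[1],
                            config$anxiety$trait$range[2])

  # money weight: group mean/SD preserved, coupled to within-group anxiety
  b_aw <- config$mediation$b_anxiety_wm
  anx_std <- (stai_state - anx_cfg[1]) / anx_cfg[2]
  wm <- dp$wm[1] + dp$wm[2] * (b_aw * anx_std + sqrt(1 - b_aw^2) * rnorm(n))
  wd <- rnorm(n, dp$wd[1], dp$wd[2])

  sc <- config$scenarios
  restaurant <- rnorm_trunc(n, sc$restaurant[[group]][1], sc$restaurant[[group]][2],
                            sc$restaurant$range[1], sc$restaurant$range[2])
  movie <- rnorm_trunc(n, sc$movie[[group]][1], sc$movie[[group]][2],
                       sc$movie$range[1], sc$movie$range[2])
  gift <- rnorm_trunc(n, sc$gift[[group]][1], sc$gift[[group]][2],
                      sc$gift$range[1], sc$gift$range[2])

  trials <- vector("list", n)
  n_impulsive <- integer(n)
  for (i in seq_len(n)) {
    pars <- ddm_params(z = z[i], a = a[i], t0 = t0[i], dc = dc[i],
                       wm = wm[i], wd = wd[i])
    pair_rows <- if (config$n_trials == nrow(menu)) seq_len(nrow(menu)) else
      sample.int(nrow(menu), config$n_trials, replace = config$n_trials > nrow(menu))
    tr <- simulate_trials(pars, menu[pair_rows, ], dt = dt)
    tr$participant_id <- ids[i]
    trials[[i]] <- tr
    n_impulsive[i] <- count_impulsive_choices(tr)
  }
  list(
    participants = tibble(
      participant_id = ids, group = group, sas_total = sas_total,
      stai_state = stai_state, stai_trait = stai_trait,
      restaurant_wait = restaurant, movie_timing = movie,
      gift_compensation = gift, extended_self = NA_real_,
      fomo_mean = NA_real_, social_threat_mean = NA_real_,
      indifference_point = NA_real_, k = NA_real_,
      n_impulsive = n_impulsive
    ),
    truth = tibble(participant_id = ids, z = z, a = a, t0 = t0, dc = dc,
                   wm = wm, wd = wd, latent_k = NA_real_),
    trials = do.call(rbind, trials),
    sas_items = items
  )
}

#' Generate a separation-experiment cohort
#'
#' Draws a full laboratory-experiment-shaped dataset: per participant,
#' latent DDM parameters from the group distributions (truncated by
#' resampling), trials simulated from those parameters over the choice
#' menu, state/trait anxiety, item-level SAS responses consistent with the
#' target total distribution and reliability (and the group-specific
#' SAS-anxiety correlation), and scenario responses with the configured
#' group shifts. Fully reproducible from `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param dt Trial-simulation step in seconds.
#' @return An `itc_cohort` list: `participants` (one row each),
#'   `trials` (long), `truth` (latent generating parameters),
#'   `sas_items` (respondent x item matrix), `menu`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L, dt = 0.001) {
  set.seed(seed)
  menu <- generate_choice_menu(config)
  n <- config$n_per_group
  ctrl <- generate_group(config, "control",
                         sprintf("C%03d", seq_len(n)), menu, dt)
  sep <- generate_group(config, "separated",
                        sprintf("S%03d", seq_len(n)), menu, dt)
  structure(list(
    participants = rbind(ctrl$participants, sep$participants),
    trials = rbind(ctrl$trials, sep$trials),
    truth = rbind(ctrl$truth, sep$truth),
    sas_items = rbind(ctrl$sas_items, sep$sas_items),
    menu = menu, config = config, seed = seed
  ), class = "itc_cohort")
}

#' Generate a titration-study cohort
#'
#' Study-1/2-shaped records: each participant has a latent lognormal
#' hyperbolic discount rate `k`; at each grid amount X the immediate
#' option is chosen with probability `plogis((X - A/(1+kD)) / temperature)`
#' (logistic response noise around the hyperbolic present value). SAS
#' totals are drawn independently of `k` by default, emulating a null
#' association between smartphone addiction and impulsivity.
#'
#' @param config A [cohort_config()] (fields under `titration`).
#' @param seed Integer seed.
#' @return An `itc_titration_cohort` list: `participants` (with scored
#'   `indifference_point`, `censored`, `k`), `responses` (long),
#'   `truth` (latent k), `config`, `seed`.
#' @export
generate_titration_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  tc <- config$titration
  n <- tc$n
  grid <- tc$grid
  A <- tc$delayed_amount
  D <- tc$delay
  latent_k <- rlnorm(n, tc$k_meanlog, tc$k_sdlog)
  pv <- A / (1 + latent_k * D)
  ids <- sprintf("T%03d", seq_len(n))
  sas_total <- rnorm_trunc(n, tc$sas[1], tc$sas[2], 11, 55)
  resp <- matrix("", n, length(grid))
  scored <- vector("list", n)
  for (i in seq_len(n)) {
    p_imm <- plogis((grid - pv[i]) / tc$temperature)
    resp[i, ] <- ifelse(runif(length(grid)) < p_imm, "immediate", "delayed")
    ser <- titration_series(resp[i, ], grid, A, D)
    ip <- indifference_point(ser)
    scored[[i]] <- ip
  }
  ip_tab <- do.call(rbind, scored)
  participants <- tibble(
    participant_id = ids, sas_total = sas_total,
    indifference_point = ip_tab$point, censored = ip_tab$censored,
    multi_switch = ip_tab$multi_switch,
    k = discount_rate_k(ip_tab$point, A, D)
  )
  responses <- tibble(
    participant_id = rep(ids, each = length(grid)),
    immediate_amount = rep(grid, n),
    response = as.vector(t(resp))
  )
  structure(list(participants = participants, responses = responses,
                 truth = tibble(participant_id = ids, latent_k = latent_k),
                 config = config, seed = seed),
            class = "itc_titration_cohort")
}

#' Generate a survey-shaped cohort (addiction, extended self, anxiety)
#'
#' Emulates the online-survey design: a smartphone-addiction continuum,
#' three candidate mediators (extended self, fear of missing out,
#' perceived social threat) each loading on addiction, and anxiety driven
#' by the extended self (plus a small direct addiction path) — so the
#' extended self is the true mediator while FoMO and social threat
#' correlate with addiction but carry no path into anxiety by default.
#'
#' @param config A [cohort_config()] (fields under `survey`).
#' @param seed Integer seed.
#' @return An `itc_survey_cohort` list with `participants` (columns
#'   `sas_total`, `extended_self`, `fomo_mean`, `social_threat_mean`,
#'   `anxiety`, plus the median-split `group`), `config`, `seed`.
#' @export
generate_survey_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  sv <- config$survey
  n <- sv$n
  # latent standardized addiction score
  z_sas <- rnorm(n)
  sas_total <- sv$sas[1] + sv$sas[2] * z_sas
  out_of_range <- which(sas_total < 11 | sas_total > 55)
  while (length(out_of_range)) {
    z_sas[out_of_range] <- rnorm(length(out_of_range))
    sas_total[out_of_range] <- sv$sas[1] + sv$sas[2] * z_sas[out_of_range]
    out_of_range <- out_of_range[sas_total[out_of_range] < 11 |
                                   sas_total[out_of_range] > 55]
  }
  gen_mediator <- function(spec) {
    std <- spec$path * z_sas + sqrt(1 - spec$path^2) * rnorm(n)
    raw <- spec$mean_sd[1] + spec$mean_sd[2] * std
    raw <- pmin(pmax(raw, spec$range[1]), spec$range[2])
    list(std = std, raw = raw)
  }
  ext <- gen_mediator(sv$extended_self)
  fomo <- gen_mediator(sv$fomo)
  social <- gen_mediator(sv$social_threat)
  av <- sv$anxiety
  lin <- av$b_extended_self * ext$std + av$b_fomo * fomo$std +
    av$b_social_threat * social$std + av$c_direct * z_sas
  v_lin <- var(lin)
  anx_std <- lin + sqrt(max(1 - v_lin, 0.05)) * rnorm(n)
  anxiety <- pmin(pmax(av$mean_sd[1] + av$mean_sd[2] * anx_std,
                       av$range[1]), av$range[2])
  split <- median_split(sas_total)
  participants <- tibble(
    participant_id = sprintf("V%03d", seq_len(n)),
    group = split$labels, sas_total = sas_total,
    extended_self = ext$raw, fomo_mean = fomo$raw,
    social_threat_mean = social$raw, anxiety = anxiety
  )
  structure(list(participants = participants, sas_median = split$median,
                 config = config, seed = seed),
            class = "itc_survey_cohort")
}

#' Generate serial-mediation data with known truth
#'
#' Linear-Gaussian structural chain `x -> m1 -> m2 -> y` with configured
#' standardized path coefficients; every variable has unit variance, so
#' standardized fits recover the configured paths and the true serial
#' indirect effect is exactly `a1 * d21 * b2`.
#'
#' @param n Sample size.
#' @param a1 Path x -> m1.
#' @param d21 Path m1 -> m2.
#' @param b2 Path m2 -> y.
#' @param a2,b1,c_prime Remaining direct paths (default 0).
#' @param x_type `"binary"` (balanced 0/1 treatment) or `"gaussian"`.
#' @param seed Integer seed.
#' @return List: `data` (tibble x, m1, m2, y) and `truth` (paths plus
#'   `ind_serial`, `ind_m1`, `ind_m2`).
#' @export
generate_mediation_truth <- function(n = 72, a1 = 0.6, d21 = 0.5, b2 = 0.4,
                                     a2 = 0, b1 = 0, c_prime = 0,
                                     x_type = c("binary", "gaussian"),
                                     seed = 1L) {
  x_type <- match.arg(x_type)
  set.seed(seed)
  x <- if (x_type == "binary") rep(c(0, 1), length.out = n) else rnorm(n)
  xs <- zstd(x)
  m1 <- a1 * xs + sqrt(max(1 - a1^2, 0.02)) * rnorm(n)
  v2 <- a2^2 + d21^2 + 2 * a2 * d21 * a1
  m2 <- a2 * xs + d21 * m1 + sqrt(max(1 - v2, 0.02)) * rnorm(n)
  cx_m2 <- a2 + d21 * a1
  cm1_m2 <- a2 * a1 + d21
  vy <- c_prime^2 + b1^2 + b2^2 +
    2 * (c_prime * b1 * a1 + c_prime * b2 * cx_m2 + b1 * b2 * cm1_m2)
  y <- c_prime * xs + b1 * m1 + b2 * m2 + sqrt(max(1 - vy, 0.02)) * rnorm(n)
  list(
    data = tibble(x = x, m1 = m1, m2 = m2, y = y),
    truth = list(a1 = a1, a2 = a2, d21 = d21, b1 = b1, b2 = b2,
                 c_prime = c_prime,
                 ind_serial = a1 * d21 * b2, ind_m1 = a1 * b1,
                 ind_m2 = a2 * b2)
  )
}

#' Write cohort tables to CSV files
#'
#' Writes `participants.csv` (participant schema), `trials.csv` (trial
#' schema) and `truth.csv` (latent generating parameters) under `dir`.
#'
#' @param cohort An `itc_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "itc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write_trials_csv(cohort$trials, file.path(dir, "trials.csv"))
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
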