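#' Fit the multi-attribute DDM to one participant's trials
#'
#' Point estimation by bounded multi-start maximum likelihood (default), or
#' posterior sampling by adaptive random-walk Metropolis (`mode = "bayes"`,
#' non-hierarchical, weak priors; point estimate = posterior mean). Six
#' parameters are estimated: `z`, `a`, `t0`, `dc`, `wm`, `wd`; the noise
#' scale stays fixed at `s`. Any subset can be pinned through `fixed`
#' (e.g. `fixed = list(z = 0.5)` for an unbiased start).
#'
#' Optimiser bounds are `a` in (0.1, 5), `z` in (0.05, 0.95), `t0` in
#' (0, min(rt) - 1 ms), weights in (-1, 1) and `dc` in (-5, 5); starts are
#' Latin-hypercube draws inside the bounds plus a centre start. Bayes-mode
#' priors: `z ~ Beta(2, 2)`, `a ~ half-normal(2)`, `t0 ~ U(0, min rt)`,
#' `dc ~ N(0, 10)`, `wm`/`wd ~ N(0, 10 / mean |attribute diff|)`.
#'
#' @param trials Trials tibble (columns `money_diff`, `delay_diff`,
#'   `choice`, `rt`). At least 20 trials with both choice categories are
#'   expected; fewer (or one-sided data) degrades the contract: a warning
#'   is emitted and `converged` is `FALSE`.
#' @param mode `"mle"` or `"bayes"`.
#' @param fixed Optional named list pinning parameters.
#' @param seed Integer seed (reproducibility of starts / chain).
#' @param s Fixed noise scale.
#' @param n_starts Number of multistarts (MLE mode).
#' @param n_iter,n_burn MCMC length and burn-in (Bayes mode).
#' @return A `ddm_fit` object: `params` ([ddm_params()] point estimate),
#'   `nll` (objective at the estimate), `converged`, `n_trials`, `mode`,
#'   and `samples` (posterior draws matrix, Bayes mode only).
#' @export
fit_ddm_individual <- function(trials, mode = c("mle", "bayes"), fixed = NULL,
                               seed = 1L, s = 1, n_starts = 8L,
                               n_iter = 4000L, n_burn = 2000L) {
  mode <- match.arg(mode)
  if (nrow(trials) == 0) stop("trial list must be non-empty")
  if (any(trials$rt <= 0)) stop("all reaction times must be positive")
  one_sided <- length(unique(as.character(trials$choice))) < 2
  if (nrow(trials) < 20 || one_sided) {
    warning("fewer than 20 trials or a single choice category: ",
            "estimates are degraded and flagged as non-converged")
  }
  md <- trials$money_diff
  dd <- trials$delay_diff
  ch <- as.integer(trials$choice == "LL")
  rt <- trials$rt
  t0_max <- max(min(rt) - 1e-3, 2e-3)

  lower <- c(z = 0.05, a = 0.1, t0 = 1e-3, dc = -5, wm = -1, wd = -1)
  upper <- c(z = 0.95, a = 5,   t0 = t0_max, dc = 5, wm = 1, wd = 1)
  par_names <- names(lower)
  is_fixed <- par_names %in% names(fixed)
  pinned <- setNames(rep(NA_real_, 6), par_names)
  if (!is.null(fixed)) pinned[names(fixed)] <- unlist(fixed)

  nll_full <- function(full) {
    .ddm_nll_cpp(full, md, dd, ch, rt, s, 1e-12, 1e-10)
  }
  expand <- function(free) {
    full <- pinned
    full[!is_fixed] <- free
    full
  }
  obj <- function(free) nll_full(expand(free))

  if (mode == "mle") {
    set.seed(seed)
    d <- sum(!is_fixed)
    grid <- lhs::randomLHS(n_starts, d)
    lo <- lower[!is_fixed]
    hi <- upper[!is_fixed]
    starts <- t(apply(grid, 1, function(u) lo + u * (hi - lo)))
    centre <- (lo + hi) / 2
    centre[names(centre) == "t0"] <- min(0.9 * min(rt), t0_max)
    starts <- rbind(centre, starts)
    # short exploration from every start, then polish the best two
    run_start <- function(st, maxit) {
      st <- pmin(pmax(st, lo + 1e-6), hi - 1e-6)
      if (!is.finite(obj(st))) return(NULL)
      res <- tryCatch(
        optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
              control = list(maxit = maxit)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) NULL else res
    }
    start_val <- apply(starts, 1, function(st)
      obj(pmin(pmax(st, lo + 1e-6), hi - 1e-6)))
    keep_starts <- head(order(start_val), 4)
    explored <- lapply(keep_starts,
                       function(i) run_start(starts[i, ], 40))
    explored <- Filter(Negate(is.null), explored)
    if (!length(explored)) stop("likelihood non-finite at every start")
    ord <- order(vapply(explored, `[[`, 0, "value"))
    best <- NULL
    for (i in head(ord, 2)) {
      res <- run_start(explored[[i]]$par, 400)
      if (is.null(res)) res <- explored[[i]]
      if (is.null(best) || res$value < best$value) best <- res
    }
    full <- expand(best$par)
    full <- setNames(as.numeric(full), names(full))
    params <- ddm_params(z = unname(full["z"]), a = unname(full["a"]),
                         t0 = unname(full["t0"]), dc = unname(full["dc"]),
                         wm = unname(full["wm"]), wd = unname(full["wd"]), s = s)
    converged <- best$convergence == 0 && is.finite(best$value) &&
      !one_sided && nrow(trials) >= 20
    out <- list(params = params, nll = best$value, converged = converged,
                n_trials = nrow(trials), mode = "mle", samples = NULL,
                seed = seed)
  } else {
    out <- fit_ddm_bayes(md, dd, ch, rt, pinned, is_fixed, lower, upper,
                         s, seed, n_iter, n_burn, nll_full, one_sided,
                         n_trials = nrow(trials))
  }
  class(out) <- "ddm_fit"
  out
}

# adaptive random-walk Metropolis on the natural scale (reflected at bounds)
fit_ddm_bayes <- function(md, dd, ch, rt, pinned, is_fixed, lower, upper,
                          s, seed, n_iter, n_burn, nll_full, one_sided,
                          n_trials) {
  set.seed(seed)
  par_names <- names(lower)
  sd_wm <- 10 / max(1, mean(abs(md)))
  sd_wd <- 10 / max(1, mean(abs(dd)))
  t0_max <- upper["t0"]
  log_prior <- function(full) {
    stats::dbeta(full["z"], 2, 2, log = TRUE) +
      stats::dnorm(full["a"], 0, 2, log = TRUE) +        # half-normal, a > 0 by bounds
      stats::dunif(full["t0"], 0, t0_max, log = TRUE) +
      stats::dnorm(full["dc"], 0, 10, log = TRUE) +
      stats::dnorm(full["wm"], 0, sd_wm, log = TRUE) +
      stats::dnorm(full["wd"], 0, sd_wd, log = TRUE)
  }
  log_post <- function(full) {
    lp <- log_prior(full)
    if (!is.finite(lp)) return(-Inf)
    -nll_full(full) + lp
  }
  free_idx <- which(!is_fixed)
  cur <- pinned
  cur[free_idx] <- (lower[free_idx] + upper[free_idx]) / 2
  cur["t0"] <- if (is_fixed[3]) cur["t0"] else min(0.9 * min(rt), t0_max) / 2
  step <- 0.1 * (upper[free_idx] - lower[free_idx])
  lp_cur <- log_post(cur)
  keep <- matrix(NA_real_, n_iter - n_burn, length(free_idx),
                 dimnames = list(NULL, par_names[free_idx]))
  acc <- 0
  for (it in seq_len(n_iter)) {
    prop <- cur
    prop[free_idx] <- cur[free_idx] + rnorm(length(free_idx), 0, step)
    # reflect into bounds
    for (j in free_idx) {
      pj <- prop[j]
      if (pj < lower[j]) pj <- lower[j] + (lower[j] - pj)
      if (pj > upper[j]) pj <- upper[j] - (pj - upper[j])
      prop[j] <- min(max(pj, lower[j] + 1e-9), upper[j] - 1e-9)
    }
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      cur <- prop
      lp_cur <- lp_prop
      acc <- acc + 1
    }
    if (it <= n_burn && it %% 100 == 0) {
      rate <- acc / 100
      step <- step * exp(rate - 0.25)   # aim near 25% acceptance
      acc <- 0
    }
    if (it > n_burn) keep[it - n_burn, ] <- cur[free_idx]
  }
  post_mean <- pinned
  post_mean[free_idx] <- colMeans(keep)
  params <- ddm_params(z = unname(post_mean["z"]), a = unname(post_mean["a"]),
                       t0 = unname(post_mean["t0"]), dc = unname(post_mean["dc"]),
                       wm = unname(post_mean["wm"]), wd = unname(post_mean["wd"]),
                       s = s)
  list(params = params, nll = nll_full(post_mean),
       converged = !one_sided && n_trials >= 20,
       n_trials = n_trials, mode = "bayes", samples = keep, seed = seed)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit (%s, %d trials, %s)\n", x$mode, x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat("NLL:", round(x$nll, 3), "\n")
  invisible(x)
}

#' Posterior-predictive summaries of a fitted DDM
#'
#' Simulates `n_sim` replicate datasets over a pair menu (one trial per
#' pair per replicate), drawing a posterior sample per replicate when the
#' fit carries draws (Bayes mode) and using the point estimate otherwise,
#' then averages the summary statistics: probability of choosing the
#' delayed reward, and mean RT of delayed (LL) and immediate (SS) choices.
#'
#' @param fit A `ddm_fit` object.
#' @param pairs A `choice_pairs` tibble.
#' @param n_sim Number of simulated datasets (default 500).
#' @param seed Integer seed.
#' @param dt Simulation step (seconds).
#' @param override Set `TRUE` to summarise a non-converged fit.
#' @return A one-row tibble: `p_ll`, `mean_rt_ll`, `mean_rt_ss` (`NA` when
#'   a choice category never occurs), `n_sim`.
#' @export
posterior_predictive_summary <- function(fit, pairs, n_sim = 500, seed = 1L,
                                         dt = 0.001, override = FALSE) {
  if (nrow(pairs) == 0) stop("pair list must be non-empty")
  if (!fit$converged && !override) {
    stop("fit did not converge; pass override = TRUE to summarise anyway")
  }
  set.seed(seed)
  p_ll <- rt_ll <- rt_ss <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    par_i <- fit$params
    if (!is.null(fit$samples)) {
      draw <- fit$samples[sample.int(nrow(fit$samples), 1L), ]
      for (nm in colnames(fit$samples)) par_i[[nm]] <- unname(draw[nm])
    }
    sim <- simulate_trials(par_i, pairs, dt = dt)
    ok <- !sim$censored
    p_ll[i] <- mean(sim$choice[ok] == "LL")
    rt_ll[i] <- mean(sim$rt[ok & sim$choice == "LL"])
    rt_ss[i] <- mean(sim$rt[ok & sim$choice == "SS"])
  }
  tibble(
    p_ll = mean(p_ll, na.rm = TRUE),
    mean_rt_ll = if (all(is.nan(rt_ll))) NA_real_ else mean(rt_ll, na.rm = TRUE),
    mean_rt_ss = if (all(is.nan(rt_ss))) NA_real_ else mean(rt_ss, na.rm = TRUE),
    n_sim = n_sim
  )
}

#' Per-parameter group contrast of fitted DDM parameters
#'
#' Compares two groups of individual fits parameter by parameter: group
#' means and SDs plus a two-group one-way F with eta squared (via
#' [oneway_f_from_groups()]).
#'
#' @param fits_a,fits_b Lists of `ddm_fit` objects (both non-empty, at
#'   least two fits each).
#' @return A tibble with one row per parameter: `parameter`, `mean_a`,
#'   `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `f`, `df1`, `df2`, `p`,
#'   `eta_sq`.
#' @export
group_weight_contrast <- function(fits_a, fits_b) {
  if (length(fits_a) < 2 || length(fits_b) < 2) {
    stop("each group needs at least two fits")
  }
  pars <- c("z", "a", "t0", "dc", "wm", "wd")
  extract <- function(fits, nm) vapply(fits, function(f) f$params[[nm]], 0)
  rows <- lapply(pars, function(nm) {
    xa <- extract(fits_a, nm)
    xb <- extract(fits_b, nm)
    an <- oneway_f_from_groups(group_stats(xa), group_stats(xb))
    tibble(parameter = nm,
           mean_a = mean(xa), sd_a = sd(xa), n_a = length(xa),
           mean_b = mean(xb), sd_b = sd(xb), n_b = length(xb),
           f = an$f, df1 = an$df1, df2 = an$df2, p = an$p, eta_sq = an$eta_sq)
  })
  do.call(rbind, rows)
}

#' Write individual fits to the fit-output CSV schema
#'
#' Columns: `participant_id`, `z`, `a`, `t0`, `dc`, `wm`, `wd`, `nll`,
#' `converged`, `mode`.
#'
#' @param fits List of `ddm_fit` objects.
#' @param ids Participant identifiers (same length as `fits`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, ids, path) {
  stopifnot(length(fits) == length(ids))
  rows <- lapply(seq_along(fits), function(i) {
    p <- fits[[i]]$params
    data.frame(participant_id = ids[i], z = p$z, a = p$a, t0 = p$t0,
               dc = p$dc, wm = p$wm, wd = p$wd, nll = fits[[i]]$nll,
               converged = fits[[i]]$converged, mode = fits[[i]]$mode)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
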