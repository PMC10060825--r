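#' Summary statistics of one group
#'
#' @param x Numeric vector (length >= 2), or pass `mean`, `sd`, `n`
#'   directly for statistics transcribed from a report.
#' @param mean,sd,n Optional explicit values (used when `x` is missing).
#' @return A `group_stats` list: `mean`, `sd` (sample SD, n-1), `n`.
#' @export
group_stats <- function(x, mean = NULL, sd = NULL, n = NULL) {
  if (!missing(x)) {
    if (length(x) < 2) stop("group needs at least two observations")
    out <- list(mean = base::mean(x), sd = stats::sd(x), n = length(x))
  } else {
    out <- list(mean = mean, sd = sd, n = n)
  }
  if (out$n < 2) stop("group size must be >= 2")
  if (out$sd < 0) stop("sd must be >= 0")
  structure(out, class = "group_stats")
}

#' Two-group one-way ANOVA from group summaries
#'
#' Pooled-variance two-group one-way F (the square of the pooled two-sample
#' t), with `df1 = 1`, `df2 = n1 + n2 - 2`, exact p from the F
#' distribution and `eta_sq = F * df1 / (F * df1 + df2)`. Works from group
#' summaries alone, so printed means/SDs/ns of a report can be re-analysed.
#'
#' @param g1,g2 [group_stats()] objects.
#' @return One-row tibble: `f`, `df1`, `df2`, `p`, `eta_sq`,
#'   `infinite_f` (TRUE when the pooled variance is zero with unequal
#'   means).
#' @examples
#' oneway_f_from_groups(group_stats(mean = 37.50, sd = 7.25, n = 36),
#'                      group_stats(mean = 29.11, sd = 4.23, n = 36))
#' @export
oneway_f_from_groups <- function(g1, g2) {
  stopifnot(inherits(g1, "group_stats"), inherits(g2, "group_stats"))
  n1 <- g1$n; n2 <- g2$n
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / df2
  diff <- g1$mean - g2$mean
  if (sp2 == 0) {
    if (diff == 0) {
      return(tibble(f = 0, df1 = 1, df2 = df2, p = 1, eta_sq = 0,
                    infinite_f = FALSE))
    }
    return(tibble(f = Inf, df1 = 1, df2 = df2, p = 0, eta_sq = 1,
                  infinite_f = TRUE))
  }
  f <- diff^2 / (sp2 * (1 / n1 + 1 / n2))
  tibble(f = f, df1 = 1, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE),
         eta_sq = eta_squared(f, 1, df2), infinite_f = FALSE)
}

#' Eta squared from an F statistic
#'
#' `eta_sq = F * df1 / (F * df1 + df2)`; for the one-way two-group design
#' this equals the between-groups share of the total sum of squares.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Proportion in `[0, 1]`.
#' @examples
#' eta_squared(35.949, 1, 70) # ~0.339
#' @export
eta_squared <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' F for the group term of the linear model `y ~ group + covariates`
#' (Type III test via `car::Anova`; identical to Type II here since the
#' model is additive). Character/factor covariates are dummy-coded,
#' numeric covariates enter linearly. With no covariates the result equals
#' [oneway_f_from_groups()] on the same data. `eta_sq` is the partial eta
#' squared of the group term.
#'
#' @param y Outcome vector.
#' @param group Two-level grouping (factor, character or 0/1).
#' @param covariates Optional data frame of covariates.
#' @return One-row tibble: `f`, `df1`, `df2`, `p`, `eta_sq`.
#' @export
ancova_group_effect <- function(y, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  dat <- data.frame(.y = y, .group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      if (is.character(covariates[[nm]])) covariates[[nm]] <- factor(covariates[[nm]])
    }
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".group", names(covariates)), collapse = " + ")
  } else {
    rhs <- ".group"
  }
  if (nrow(dat) <= length(attr(stats::terms(stats::reformulate(rhs)), "term.labels")) + 2) {
    stop("too few observations for the model")
  }
  fit <- lm(stats::reformulate(rhs, response = ".y"), data = dat)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    stop("rank-deficient model; aliased term(s): ",
         paste(names(coef(fit))[aliased], collapse = ", "))
  }
  tab <- car::Anova(fit, type = 3)
  i <- which(rownames(tab) == ".group")
  f <- tab[i, "F value"]
  df1 <- tab[i, "Df"]
  df2 <- tab["Residuals", "Df"]
  tibble(f = f, df1 = df1, df2 = df2,
         p = tab[i, "Pr(>F)"], eta_sq = eta_squared(f, df1, df2))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return One-row tibble: `r`, `p` (two-sided, t transform with n-2 df),
#'   `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a summed scale:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total score))`.
#' Can be negative for incoherent item sets.
#'
#' @param items Respondent-by-item numeric matrix (>= 2 items, >= 2
#'   respondents).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("need at least two items")
  if (nrow(items) < 2) stop("need at least two respondents")
  total_var <- var(rowSums(items))
  if (total_var == 0) stop("zero total-score variance")
  (k / (k - 1)) * (1 - sum(apply(items, 2, var)) / total_var)
}

#' Median split into low/high groups
#'
#' Scores at or below the median are labelled `"low"`, scores above it
#' `"high"` (ties go to `"low"`).
#'
#' @param scores Numeric vector (n >= 2).
#' @return List: `labels` (factor low/high), `median`, `degenerate`
#'   (TRUE when one group is empty, e.g. all-equal scores).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least two scores")
  med <- median(scores)
  labels <- factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
  degenerate <- any(table(labels) == 0)
  if (degenerate) warning("median split produced an empty group")
  list(labels = labels, median = med, degenerate = degenerate)
}

# ---- bootstrap mediation ---------------------------------------------------

zstd <- function(x) (x - mean(x)) / sd(x)

# OLS coefficients without lm() overhead (intercept added here)
ols_coef <- function(X, y) {
  fit <- stats::.lm.fit(cbind(1, X), y)
  if (fit$rank < ncol(X) + 1) stop("collinear predictors in mediation model")
  fit$coefficients[-1]
}

check_mediation_input <- function(vars) {
  n <- unique(vapply(vars, length, 0L))
  if (length(n) != 1) stop("all variables must have equal length")
  if (n < 10) stop("mediation requires at least 10 observations")
  if (any(vapply(vars, sd, 0) == 0)) stop("constant variable in mediation model")
  n
}

percentile_ci <- function(draws, conf) {
  alpha <- (1 - conf) / 2
  unname(quantile(draws, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Simple mediation with percentile bootstrap
#'
#' One-mediator path model in the PROCESS Model 4 style: `a` from
#' `m ~ x`, `b` and `c'` from `y ~ x + m`, all ordinary least squares;
#' indirect effect `a * b` with SE and percentile confidence interval from
#' case-resampled bootstrap replicates. Variables are z-scored (sample SD)
#' before fitting when `standardize = TRUE` (once, on the original data;
#' resampling happens on the standardized data).
#'
#' @param x,m,y Numeric vectors of equal length.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed (deterministic CI under a fixed seed).
#' @param standardize Z-score all variables first (default TRUE).
#' @param conf Confidence level (default 0.95).
#' @return A `mediation_result` list: `paths` (a, b, c_prime, c_total),
#'   `indirect`, `boot_se`, `ci_low`, `ci_high`, `n_boot`, `conf`,
#'   `seed`, `n`.
#' @export
mediation_simple <- function(x, m, y, n_boot = 5000, seed = 1L,
                             standardize = TRUE, conf = 0.95) {
  n <- check_mediation_input(list(x = x, m = m, y = y))
  if (standardize) { x <- zstd(x); m <- zstd(m); y <- zstd(y) }
  est <- function(x, m, y) {
    a <- ols_coef(cbind(x), m)[1]
    bc <- ols_coef(cbind(x, m), y)
    c(a = a, b = bc[2], c_prime = bc[1], indirect = a * bc[2])
  }
  point <- est(x, m, y)
  c_total <- ols_coef(cbind(x), y)[1]
  set.seed(seed)
  draws <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(est(x[idx], m[idx], y[idx])[["indirect"]],
             error = function(e) NA_real_)
  }, 0)
  ci <- percentile_ci(draws, conf)
  structure(list(
    model = "simple",
    paths = c(a = unname(point["a"]), b = unname(point["b"]),
              c_prime = unname(point["c_prime"]), c_total = unname(c_total)),
    indirect = unname(point["indirect"]),
    boot_se = sd(draws, na.rm = TRUE),
    ci_low = ci[1], ci_high = ci[2],
    n_boot = n_boot, conf = conf, seed = seed, n = n
  ), class = "mediation_result")
}

#' Serial two-mediator mediation with percentile bootstrap
#'
#' PROCESS Model 6 style chain `x -> m1 -> m2 -> y`. Paths: `a1`
#' (`m1 ~ x`), `a2` and `d21` (`m2 ~ x + m1`), `c'`, `b1`, `b2`
#' (`y ~ x + m1 + m2`). The serial indirect effect is `a1 * d21 * b2`; the
#' two single-mediator indirect paths `a1 * b1` and `a2 * b2` are also
#' reported, each with a percentile bootstrap CI.
#'
#' @inheritParams mediation_simple
#' @param m1,m2 The first and second mediator in causal order.
#' @return A `mediation_result` list; `indirect_table` is a tibble with
#'   one row per indirect path (`x->m1->y`, `x->m2->y`,
#'   `x->m1->m2->y`), and `indirect`/`boot_se`/`ci_low`/`ci_high` refer
#'   to the serial path.
#' @export
mediation_serial <- function(x, m1, m2, y, n_boot = 5000, seed = 1L,
                             standardize = TRUE, conf = 0.95) {
  n <- check_mediation_input(list(x = x, m1 = m1, m2 = m2, y = y))
  if (standardize) { x <- zstd(x); m1 <- zstd(m1); m2 <- zstd(m2); y <- zstd(y) }
  est <- function(x, m1, m2, y) {
    a1 <- ols_coef(cbind(x), m1)[1]
    m2c <- ols_coef(cbind(x, m1), m2)
    yc <- ols_coef(cbind(x, m1, m2), y)
    c(a1 = a1, a2 = m2c[1], d21 = m2c[2],
      c_prime = yc[1], b1 = yc[2], b2 = yc[3],
      ind_m1 = a1 * yc[2], ind_m2 = m2c[1] * yc[3],
      ind_serial = a1 * m2c[2] * yc[3])
  }
  point <- est(x, m1, m2, y)
  c_total <- ols_coef(cbind(x), y)[1]
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("ind_m1", "ind_m2", "ind_serial")))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_i <- tryCatch(est(x[idx], m1[idx], m2[idx], y[idx]),
                      error = function(e) NULL)
    if (!is.null(rep_i)) draws[i, ] <- rep_i[c("ind_m1", "ind_m2", "ind_serial")]
  }
  cis <- apply(draws, 2, percentile_ci, conf = conf)
  ind_tab <- tibble(
    path = c("x->m1->y", "x->m2->y", "x->m1->m2->y"),
    estimate = unname(point[c("ind_m1", "ind_m2", "ind_serial")]),
    boot_se = apply(draws, 2, sd, na.rm = TRUE),
    ci_low = cis[1, ], ci_high = cis[2, ]
  )
  structure(list(
    model = "serial",
    paths = c(point[c("a1", "a2", "d21", "b1", "b2", "c_prime")],
              c_total = unname(c_total)),
    indirect_table = ind_tab,
    indirect = unname(point["ind_serial"]),
    boot_se = ind_tab$boot_se[3],
    ci_low = ind_tab$ci_low[3], ci_high = ind_tab$ci_high[3],
    n_boot = n_boot, conf = conf, seed = seed, n = n
  ), class = "mediation_result")
}

#' Parallel multiple-mediator mediation with percentile bootstrap
#'
#' PROCESS Model 4 with several mediators entered in parallel: each
#' `a_j` from `m_j ~ x`, all `b_j` and `c'` from `y ~ x + m_1 + ... +
#' m_k`; per-mediator indirect effects `a_j * b_j` with percentile
#' bootstrap CIs.
#'
#' @inheritParams mediation_simple
#' @param m Matrix or data frame of mediators (one column each).
#' @return A `mediation_result` list with an `indirect_table` of one row
#'   per mediator.
#' @export
mediation_parallel <- function(x, m, y, n_boot = 5000, seed = 1L,
                               standardize = TRUE, conf = 0.95) {
  m <- as.matrix(m)
  k <- ncol(m)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("m", seq_len(k))
  vars <- c(list(x = x), lapply(seq_len(k), function(j) m[, j]), list(y = y))
  n <- check_mediation_input(vars)
  if (standardize) {
    x <- zstd(x); y <- zstd(y)
    m <- apply(m, 2, zstd)
  }
  est <- function(x, m, y) {
    a <- vapply(seq_len(k), function(j) ols_coef(cbind(x), m[, j])[1], 0)
    yc <- ols_coef(cbind(x, m), y)
    b <- yc[-1]
    c(a * b, c_prime = yc[1])
  }
  point <- est(x, m, y)
  c_total <- ols_coef(cbind(x), y)[1]
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, nm))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_i <- tryCatch(est(x[idx], m[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
    if (!is.null(rep_i)) draws[i, ] <- rep_i[seq_len(k)]
  }
  cis <- apply(draws, 2, percentile_ci, conf = conf)
  ind_tab <- tibble(
    path = paste0("x->", nm, "->y"),
    estimate = unname(point[seq_len(k)]),
    boot_se = apply(draws, 2, sd, na.rm = TRUE),
    ci_low = cis[1, ], ci_high = cis[2, ]
  )
  structure(list(
    model = "parallel",
    paths = c(c_prime = unname(point["c_prime"]), c_total = unname(c_total)),
    indirect_table = ind_tab,
    indirect = ind_tab$estimate,
    boot_se = ind_tab$boot_se,
    ci_low = ind_tab$ci_low, ci_high = ind_tab$ci_high,
    n_boot = n_boot, conf = conf, seed = seed, n = n
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("%s mediation (n = %d, %d bootstrap resamples, %.0f%% CI)\n",
              x$model, x$n, x$n_boot, 100 * x$conf))
  cat("paths:\n")
  print(round(x$paths, 4))
  if (!is.null(x$indirect_table)) {
    cat("indirect effects:\n")
    print(x$indirect_table)
  } else {
    cat(sprintf("indirect = %.4f, boot SE = %.4f, CI [%.4f, %.4f]\n",
                x$indirect, x$boot_se, x$ci_low, x$ci_high))
  }
  invisible(x)
}
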