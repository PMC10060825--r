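#' DDM parameter set
#'
#' The multi-attribute drift diffusion model has six free parameters: the
#' relative starting point `z` (fraction of the boundary separation, 0.5 =
#' unbiased), boundary separation `a`, non-decision time `t0` (seconds),
#' drift constant `dc`, and the attribute weights `wm` (on the money
#' difference, evidence per second per money unit) and `wd` (on the delay
#' difference, evidence per second per day). The diffusion noise scale `s`
#' is fixed (default 1) and never fitted: it is non-identifiable jointly
#' with `a` and the drift parameters, so all fitted values are on the
#' `s = 1` scale.
#'
#' @param z Relative starting point in (0, 1).
#' @param a Boundary separation, > 0.
#' @param t0 Non-decision time in seconds, >= 0.
#' @param dc Drift constant (evidence/second).
#' @param wm Weight on the money difference.
#' @param wd Weight on the delay difference.
#' @param s Fixed diffusion noise scale, > 0.
#' @return An object of class `ddm_params` (named list).
#' @examples
#' ddm_params(z = 0.5, a = 1.5, t0 = 0.3, dc = 0, wm = 0.047, wd = -0.009)
#' @export
ddm_params <- function(z = 0.5, a = 1.5, t0 = 0.3, dc = 0, wm = 0, wd = 0, s = 1) {
  p <- list(z = z, a = a, t0 = t0, dc = dc, wm = wm, wd = wd, s = s)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

validate_ddm_params <- function(p) {
  stopifnot(is.list(p))
  if (!(p$a > 0)) stop("boundary separation a must be > 0")
  if (!(p$z > 0 && p$z < 1)) stop("relative starting point z must lie in (0, 1)")
  if (p$t0 < 0) stop("non-decision time t0 must be >= 0")
  if (!(p$s > 0)) stop("noise scale s must be > 0")
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Multi-attribute DDM parameters (noise s =", x$s, ")\n")
  v <- unlist(x[c("z", "a", "t0", "dc", "wm", "wd")])
  print(round(v, 4))
  invisible(x)
}

#' Attribute-weighted drift rate
#'
#' The drift rate is a linear function of the attribute differences of the
#' option pair: `v = dc + wm * money_diff + wd * delay_diff`. Positive
#' drift favours the larger-later option (upper boundary).
#'
#' @param params A [ddm_params()] object.
#' @param pairs A `choice_pairs` tibble (or any data frame with
#'   `money_diff` and `delay_diff` columns).
#' @return Numeric vector of drift rates, one per pair. May be negative.
#' @examples
#' p <- ddm_params(dc = 0, wm = 0.047, wd = -0.009)
#' drift_rate(p, choice_pairs(17, 0, 38, 30)) # 0.047*21 - 0.009*30
#' @export
drift_rate <- function(params, pairs) {
  validate_ddm_params(params)
  params$dc + params$wm * pairs$money_diff + params$wd * pairs$delay_diff
}

#' Closed-form probability of absorbing at the upper (LL) boundary
#'
#' For a diffusion with drift `v`, boundaries at 0 and `a`, start `z * a`
#' and noise `s`, the probability of reaching the upper boundary is
#' `(1 - exp(-2 v z a / s^2)) / (1 - exp(-2 v a / s^2))`, with the limit
#' `z` at `v = 0`. Used as the analytic oracle for the trial simulator.
#'
#' @param v Drift rate (vectorised).
#' @param a Boundary separation, > 0.
#' @param z Relative starting point in (0, 1).
#' @param s Noise scale, > 0.
#' @return Probability in (0, 1) (limits 0/1 returned boundedly for
#'   extreme `|v| * a / s^2`).
#' @examples
#' choice_probability(v = 1, a = 2, z = 0.5) # ~0.8808
#' @export
choice_probability <- function(v, a, z, s = 1) {
  stopifnot(a > 0, z > 0, z < 1, s > 0)
  x <- 2 * v * a / s^2
  out <- numeric(length(x))
  tiny <- abs(x) < 1e-9
  out[tiny] <- z
  big_neg <- x < -500            # expm1(-x) would overflow
  out[big_neg] <- exp(x[big_neg] * (1 - z))
  rest <- !tiny & !big_neg
  out[rest] <- expm1(-x[rest] * z) / expm1(-x[rest])
  pmin(pmax(out, 0), 1)
}

#' Wiener first-passage-time density
#'
#' Density of the decision time (RT minus non-decision time) at one
#' absorbing boundary of the diffusion. Evaluated by a dual series: a
#' small-time and a large-time expansion of the dimensionless kernel, with
#' an accuracy-based switch (truncation tolerance `err`, default 1e-10)
#' choosing whichever needs fewer terms. Both branches can be forced via
#' `method` for cross-checking.
#'
#' The upper and lower branch densities integrate jointly to 1, and the
#' upper-branch mass equals [choice_probability()].
#'
#' @param t Decision times (seconds, > 0); vectorised.
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param z Relative starting point.
#' @param s Noise scale.
#' @param boundary `"upper"` (LL) or `"lower"` (SS).
#' @param err Series truncation tolerance.
#' @param method `"auto"`, `"small"` (force small-time series) or
#'   `"large"` (force large-time series).
#' @return Nonnegative densities, one per `t`.
#' @examples
#' wfpt_density(0.5, v = 1, a = 2, z = 0.5, boundary = "upper")
#' @export
wfpt_density <- function(t, v, a, z, s = 1, boundary = c("upper", "lower"),
                         err = 1e-10, method = c("auto", "small", "large")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  stopifnot(a > 0, z > 0, z < 1, s > 0)
  if (any(t <= 0)) stop("decision times must be > 0")
  .wfpt_density_cpp(as.numeric(t), v, a, z, s,
                    as.integer(boundary == "upper"), err,
                    match(method, c("auto", "small", "large")) - 1L)
}

#' Simulate trials from the multi-attribute DDM
#'
#' Path-level simulation by the Euler-Maruyama scheme (increments
#' `v * dt + s * sqrt(dt) * N(0,1)`) with a Brownian-bridge crossing
#' correction inside every step, so simulated choice fractions converge to
#' [choice_probability()] at O(dt) rather than O(sqrt(dt)). Decision times
#' exceeding `cap` are censored and flagged.
#'
#' @param params A [ddm_params()] object.
#' @param pairs A `choice_pairs` tibble; one trial is simulated per row.
#' @param dt Time step in seconds (default 0.001).
#' @param cap Censoring cap on the decision time in seconds (default 20).
#' @return A tibble with the pair columns plus `choice` (factor `"SS"` /
#'   `"LL"`, `NA` if censored), `rt` (= crossing time + `t0`) and
#'   `censored`. Seeded by the R RNG (`set.seed()`).
#' @examples
#' set.seed(1)
#' p <- ddm_params(z = 0.5, a = 1.5, t0 = 0.3, wm = 0.05, wd = -0.01)
#' simulate_trials(p, choice_pairs(17, 0, 38, 30))
#' @export
simulate_trials <- function(params, pairs, dt = 0.001, cap = 20) {
  validate_ddm_params(params)
  stopifnot(dt > 0, cap > 0)
  v <- drift_rate(params, pairs)
  sim <- .sim_ddm_cpp(v, params$a, params$z, params$t0, params$s, dt, cap)
  out <- as_tibble(pairs)
  out$choice <- factor(ifelse(sim$choice == 1L, "LL", "SS"), levels = c("SS", "LL"))
  out$rt <- sim$rt
  out$censored <- sim$censored
  out
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(params, pairs, dt = 0.001, cap = 20) {
  simulate_trials(params, pairs[1, , drop = FALSE], dt = dt, cap = cap)
}

#' Negative log-likelihood of trial data under the DDM
#'
#' Sums `-log` WFPT densities over trials, evaluating each trial at its
#' observed boundary (LL = upper, SS = lower) with the drift implied by its
#' attribute differences. Trials whose RT does not exceed `t0` contribute a
#' floored density (default 1e-12) so the objective stays finite.
#'
#' @param params A [ddm_params()] object.
#' @param trials A tibble with columns `money_diff`, `delay_diff`,
#'   `choice` (`"SS"`/`"LL"`) and `rt` (seconds, > 0).
#' @param floor_dens Density floor.
#' @return Scalar negative log-likelihood.
#' @export
ddm_negloglik <- function(params, trials, floor_dens = 1e-12) {
  validate_ddm_params(params)
  if (nrow(trials) == 0) stop("trial list must be non-empty")
  if (any(trials$rt <= 0)) stop("all reaction times must be positive")
  .ddm_nll_cpp(c(params$z, params$a, params$t0, params$dc, params$wm, params$wd),
               trials$money_diff, trials$delay_diff,
               as.integer(trials$choice == "LL"), trials$rt,
               params$s, floor_dens, 1e-10)
}
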