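#' Titration series for delay discounting
#'
#' One participant's responses to an ascending titration: "X now, or
#' `delayed_amount` in `delay` days?" for X running over
#' `immediate_amounts` (default 10, 20, ..., 200 against 200 in 60 days).
#'
#' @param responses Character vector of `"immediate"` / `"delayed"`
#'   choices, one per grid amount.
#' @param immediate_amounts Strictly ascending grid of immediate amounts.
#' @param delayed_amount Fixed delayed amount.
#' @param delay Delay of the fixed option in days.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(responses,
                             immediate_amounts = seq(10, 200, by = 10),
                             delayed_amount = 200, delay = 60) {
  responses <- as.character(responses)
  if (length(responses) == 0) stop("responses must be non-empty")
  if (length(responses) != length(immediate_amounts)) {
    stop("responses and immediate_amounts must have the same length")
  }
  if (any(diff(immediate_amounts) <= 0)) {
    stop("immediate_amounts must be strictly ascending")
  }
  if (!all(responses %in% c("immediate", "delayed"))) {
    stop("responses must be 'immediate' or 'delayed'")
  }
  structure(list(responses = responses,
                 immediate_amounts = immediate_amounts,
                 delayed_amount = delayed_amount, delay = delay),
            class = "titration_series")
}

#' Indifference point of a titration series
#'
#' Under the monotone-switch rule the indifference point is the midpoint
#' between the largest immediate amount at which the delayed option was
#' still chosen and the smallest immediate amount accepted. A series that
#' never switches is censored: all-delayed responders get the grid maximum
#' plus half a step, all-immediate responders the grid minimum minus half a
#' step (floored at 0). A non-monotone series (several switches) is scored
#' at the midpoint bracketing the first switch and flagged.
#'
#' @param series A [titration_series()].
#' @return One-row tibble: `point` (money units), `censored`
#'   (`"none"`/`"low"`/`"high"`), `multi_switch`, `n_switches`.
#' @examples
#' resp <- ifelse(seq(10, 200, 10) <= 100, "delayed", "immediate")
#' indifference_point(titration_series(resp)) # point = 105
#' @export
indifference_point <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  imm <- series$responses == "immediate"
  grid <- series$immediate_amounts
  n <- length(grid)
  switches <- which(diff(imm) != 0)
  n_sw <- length(switches)
  half_step <- mean(diff(grid)) / 2
  if (n_sw == 0) {
    if (all(imm)) {
      return(tibble(point = max(grid[1] - half_step, 0), censored = "low",
                    multi_switch = FALSE, n_switches = 0L))
    }
    return(tibble(point = grid[n] + half_step, censored = "high",
                  multi_switch = FALSE, n_switches = 0L))
  }
  i <- switches[1]
  tibble(point = (grid[i] + grid[i + 1]) / 2, censored = "none",
         multi_switch = n_sw > 1, n_switches = as.integer(n_sw))
}

#' Discounting rate from an indifference point
#'
#' Under the hyperbolic discounting model `V = A / (1 + k D)` (the
#' standard delay-discounting form), the rate implied by indifference
#' value `V` for amount `A` at delay `D` days is `k = (A / V - 1) / D` per
#' day. The exponential model `V = A exp(-k D)` is available behind
#' `form = "exponential"` (`k = log(A / V) / D`).
#'
#' @param indifference Indifference value `V`, in (0, `delayed_amount`].
#' @param delayed_amount Delayed amount `A`.
#' @param delay Delay `D` in days (> 0).
#' @param form `"hyperbolic"` (default) or `"exponential"`.
#' @return Per-day discount rate `k >= 0`; 0 iff `V == A`.
#' @examples
#' discount_rate_k(105, 200, 60) # ~0.01508
#' @export
discount_rate_k <- function(indifference, delayed_amount = 200, delay = 60,
                            form = c("hyperbolic", "exponential")) {
  form <- match.arg(form)
  if (any(indifference <= 0)) stop("indifference value must be > 0")
  if (any(indifference > delayed_amount)) {
    stop("indifference value cannot exceed the delayed amount")
  }
  if (delay <= 0) stop("delay must be > 0")
  if (form == "hyperbolic") {
    (delayed_amount / indifference - 1) / delay
  } else {
    log(delayed_amount / indifference) / delay
  }
}

#' Count impulsive (immediate) choices
#'
#' The impulsivity score of the binary choice task: the number of trials
#' where the smaller-sooner reward was selected.
#'
#' @param trials Trials tibble with a `choice` column (`"SS"`/`"LL"`).
#' @return Integer count in `[0, nrow(trials)]`.
#' @export
count_impulsive_choices <- function(trials) {
  sum(trials$choice == "SS", na.rm = TRUE)
}

#' Standardized impulsive-purchase scores
#'
#' Scores the three purchase scenarios against the supplied cohort:
#' restaurant waiting time is reverse-coded as `65 - wait` (5-60 min
#' scale) before z-scoring, the movie timing scale is reverse-coded as
#' `101 - timing` (1 = before the deadline is the impulsive end), and the
#' gift compensation amount is kept as-is (more expected compensation =
#' more impulsive). Standardization is against the cohort passed in.
#'
#' @param responses Data frame with columns `restaurant_wait` (5-60),
#'   `movie_timing` (1-100) and `gift_compensation` (1-50), one row per
#'   participant.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return Tibble of z-scores: `restaurant_imp`, `movie_imp`, `gift_imp`.
#' @export
impulsive_purchase_score <- function(responses, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("restaurant_wait", "movie_timing", "gift_compensation") %in%
                  names(responses)))
  check_range <- function(x, lo, hi, nm) {
    if (any(x < lo | x > hi)) stop(nm, " responses outside [", lo, ", ", hi, "]")
  }
  check_range(responses$restaurant_wait, 5, 60, "restaurant_wait")
  check_range(responses$movie_timing, 1, 100, "movie_timing")
  check_range(responses$gift_compensation, 1, 50, "gift_compensation")
  zs <- function(x) {
    s <- if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize: cohort standard deviation is zero")
    }
    (x - mean(x)) / s
  }
  tibble(
    restaurant_imp = zs(65 - responses$restaurant_wait),
    movie_imp = zs(101 - responses$movie_timing),
    gift_imp = zs(responses$gift_compensation)
  )
}
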