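#' Intertemporal choice pairs
#'
#' A choice pair is one smaller-sooner (SS) / larger-later (LL) option pair
#' of a binary intertemporal choice task, e.g. "$17 today, or $38 in 30
#' days". The derived attribute differences `money_diff = amount_ll -
#' amount_ss` and `delay_diff = delay_ll - delay_ss` are the inputs to the
#' multi-attribute drift rate.
#'
#' @param amount_ss Immediate (smaller-sooner) amount, money units; > 0.
#' @param delay_ss Delay of the sooner option in days (usually 0).
#' @param amount_ll Delayed (larger-later) amount; must exceed `amount_ss`.
#' @param delay_ll Delay of the later option in days; must exceed `delay_ss`.
#'
#' @return A tibble with class `choice_pairs` and columns `amount_ss`,
#'   `delay_ss`, `amount_ll`, `delay_ll`, `money_diff`, `delay_diff`.
#'   All arguments are recycled to a common length, so a whole menu can be
#'   built in one call.
#' @examples
#' choice_pairs(17, 0, 38, 30)
#' @export
choice_pairs <- function(amount_ss, delay_ss = 0, amount_ll, delay_ll) {
  n <- max(length(amount_ss), length(delay_ss), length(amount_ll), length(delay_ll))
  out <- tibble(
    amount_ss = rep_len(as.numeric(amount_ss), n),
    delay_ss  = rep_len(as.numeric(delay_ss), n),
    amount_ll = rep_len(as.numeric(amount_ll), n),
    delay_ll  = rep_len(as.numeric(delay_ll), n)
  )
  out$money_diff <- out$amount_ll - out$amount_ss
  out$delay_diff <- out$delay_ll - out$delay_ss
  validate_choice_pairs(out)
  class(out) <- c("choice_pairs", class(out))
  out
}

validate_choice_pairs <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("amount_ss", "delay_ss", "amount_ll", "delay_ll",
           "money_diff", "delay_diff")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("choice pairs are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$amount_ss <= 0)) stop("amount_ss must be > 0")
  if (any(x$money_diff <= 0)) stop("amount_ll must exceed amount_ss")
  if (any(x$delay_ss < 0)) stop("delay_ss must be >= 0")
  if (any(x$delay_diff <= 0)) stop("delay_ll must exceed delay_ss")
  invisible(x)
}

#' Read and write trial-level CSV files
#'
#' The trial CSV schema has one row per choice with columns
#' `participant_id`, `amount_ss`, `delay_ss`, `amount_ll`, `delay_ll`,
#' `choice` (0 = SS/immediate, 1 = LL/delayed) and `rt_seconds`.
#'
#' @param trials A tibble of trials as produced by [simulate_trials()] or
#'   [generate_cohort()] (columns `participant_id`, pair columns, `choice`
#'   with values `"SS"`/`"LL"`, `rt`).
#' @param path File path.
#' @return `read_trials_csv()` returns a trials tibble with factor `choice`
#'   and derived `money_diff`/`delay_diff`; `write_trials_csv()` returns
#'   `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  out <- data.frame(
    participant_id = trials$participant_id,
    amount_ss = trials$amount_ss,
    delay_ss = trials$delay_ss,
    amount_ll = trials$amount_ll,
    delay_ll = trials$delay_ll,
    choice = as.integer(trials$choice == "LL"),
    rt_seconds = trials$rt
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble(
    participant_id = raw$participant_id,
    amount_ss = raw$amount_ss,
    delay_ss = raw$delay_ss,
    amount_ll = raw$amount_ll,
    delay_ll = raw$delay_ll,
    money_diff = raw$amount_ll - raw$amount_ss,
    delay_diff = raw$delay_ll - raw$delay_ss,
    choice = factor(ifelse(raw$choice == 1, "LL", "SS"), levels = c("SS", "LL")),
    rt = raw$rt_seconds
  )
  if (any(out$rt <= 0)) stop("all reaction times must be positive")
  out
}
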