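#' Pairwise comparison verdicts
#'
#' A pair verdict records the outcome of comparing one arm-A patient against
#' one arm-B patient on a single endpoint. The four possible outcomes are
#' `"A_wins"`, `"B_wins"`, `"neutral"` (no difference at this endpoint) and
#' `"uninformative"` (the ordering cannot be determined from the observed
#' data, e.g. because of censoring or missingness). Neutral and uninformative
#' pairs both cascade to the next endpoint of a prioritized hierarchy; they
#' are tracked separately for reporting.
#'
#' @name pair-verdicts
#' @keywords internal
NULL

# verdict codes used internally by the engine (integer matrices)
.VERDICT_A <- 1L
.VERDICT_B <- 2L
.VERDICT_NEUTRAL <- 3L
.VERDICT_UNINF <- 4L

.verdict_labels <- c("A_wins", "B_wins", "neutral", "uninformative")

verdict_label <- function(code) .verdict_labels[code]

#' Compare two censored survival observations with a clinical-relevance margin
#'
#' Gehan-style scoring of a single (arm A, arm B) patient pair on a
#' higher-is-better time-to-event endpoint such as overall survival. A patient
#' wins when their *observed* time (event or censoring) exceeds the other
#' patient's observed *event* time by at least the margin `tau`: a censored
#' winner is allowed because their survival past that point was observed.
#' Two events closer together than `tau` (or exactly tied) are neutral; any
#' configuration in which the ordering would depend on what happened after a
#' censoring time is uninformative.
#'
#' With `tau = 0` and no censoring the rule reduces to strict comparison of
#' event times (the Mann-Whitney kernel); exact ties are neutral.
#'
#' The alternative reading `censoring = "neutral"` classifies every pair
#' containing at least one censored observation as neutral outright, and only
#' scores pairs in which both patients had the event.
#'
#' @param a,b Length-2 vectors or lists with elements `time` (months, >= 0)
#'   and `event` (logical; `TRUE` if the event was observed).
#' @param tau Non-negative clinical-relevance margin in months. The default 1
#'   treats differences of less than one month between two events as no
#'   difference.
#' @param censoring `"gehan"` (default) or `"neutral"`; see Details.
#' @return A character scalar: one of `"A_wins"`, `"B_wins"`, `"neutral"`,
#'   `"uninformative"`.
#' @examples
#' compare_survival(list(time = 40, event = TRUE), list(time = 20, event = TRUE))
#' compare_survival(list(time = 30.5, event = TRUE), list(time = 30, event = TRUE))
#' compare_survival(list(time = 60, event = FALSE), list(time = 30, event = TRUE))
#' @export
compare_survival <- function(a, b, tau = 1, censoring = c("gehan", "neutral")) {
  censoring <- match.arg(censoring)
  ta <- as.numeric(a[["time"]]); ea <- isTRUE(as.logical(a[["event"]]))
  tb <- as.numeric(b[["time"]]); eb <- isTRUE(as.logical(b[["event"]]))
  check_pair_times(ta, tb, tau)
  if (censoring == "neutral" && !(ea && eb)) return("neutral")
  d <- ta - tb
  a_wins <- eb && d >= tau && d > 0
  b_wins <- ea && -d >= tau && d < 0
  if (a_wins) return("A_wins")
  if (b_wins) return("B_wins")
  if (ea && eb) return("neutral")
  "uninformative"
}

#' Compare two cumulative-incidence observations (lower is better)
#'
#' Scores a single pair on a lower-is-better time-to-first-event endpoint such
#' as locoregional recurrence or distant metastasis. A patient wins when the
#' other patient had the event and they themselves were observed event-free
#' (or had their own event) at least `tau` months beyond the other's event
#' time. Two events less than `tau` apart are neutral, as are pairs in which
#' both patients remained event-free throughout their observation. Death
#' without the event is handled upstream as censoring at the death time.
#'
#' @inheritParams compare_survival
#' @param a,b Length-2 vectors or lists with elements `time` and `event`,
#'   where `event = TRUE` means the (undesirable) event occurred at `time` and
#'   `event = FALSE` means the patient was event-free through `time`.
#' @return A character scalar verdict.
#' @examples
#' compare_incidence(list(time = 60, event = FALSE), list(time = 12, event = TRUE))
#' compare_incidence(list(time = 60, event = FALSE), list(time = 58, event = FALSE))
#' compare_incidence(list(time = 12.4, event = TRUE), list(time = 12, event = TRUE))
#' @export
compare_incidence <- function(a, b, tau = 1, censoring = c("gehan", "neutral")) {
  censoring <- match.arg(censoring)
  ta <- as.numeric(a[["time"]]); ea <- isTRUE(as.logical(a[["event"]]))
  tb <- as.numeric(b[["time"]]); eb <- isTRUE(as.logical(b[["event"]]))
  check_pair_times(ta, tb, tau)
  if (!ea && !eb) return("neutral")
  if (censoring == "neutral" && !(ea && eb)) return("neutral")
  d <- ta - tb
  a_wins <- eb && d >= tau && d > 0
  b_wins <- ea && -d >= tau && d < 0
  if (a_wins) return("A_wins")
  if (b_wins) return("B_wins")
  if (ea && eb) return("neutral")
  "uninformative"
}

#' Compare a binary endpoint
#'
#' `TRUE` (e.g. complete remission) beats `FALSE`; equal values are neutral;
#' a missing value on either side makes the pair uninformative.
#'
#' @param a,b Logical scalars, possibly `NA`.
#' @return A character scalar verdict.
#' @examples
#' compare_binary(TRUE, FALSE)
#' compare_binary(NA, FALSE)
#' @export
compare_binary <- function(a, b) {
  if (is.na(a) || is.na(b)) return("uninformative")
  if (a && !b) return("A_wins")
  if (!a && b) return("B_wins")
  "neutral"
}

#' Compare an ordinal endpoint
#'
#' Strict inequality in the favorable direction wins; equality is neutral;
#' a missing value on either side makes the pair uninformative. Used for
#' maximum CTCAE toxicity grade (`direction = "lower_better"`) and
#' quality-of-life change scores (`direction = "higher_better"`).
#'
#' @param a,b Numeric scalars, possibly `NA`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return A character scalar verdict.
#' @examples
#' compare_ordinal(2, 4, direction = "lower_better")
#' compare_ordinal(10, 10, direction = "higher_better")
#' @export
compare_ordinal <- function(a, b, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (is.na(a) || is.na(b)) return("uninformative")
  d <- if (direction == "higher_better") a - b else b - a
  if (d > 0) return("A_wins")
  if (d < 0) return("B_wins")
  "neutral"
}

check_pair_times <- function(ta, tb, tau) {
  if (is.na(ta) || is.na(tb) || ta < 0 || tb < 0) {
    rlang::abort("times must be finite and non-negative")
  }
  if (is.na(tau) || tau < 0) rlang::abort("`tau` must be non-negative")
  invisible(NULL)
}

# ---- vectorized scorers (engine internals) ---------------------------------
#
# Each returns an n_a x n_b integer matrix of verdict codes; row i compares
# patient i in the A role against column patient j in the B role. Written as
# whole-matrix boolean algebra, independently of the scalar rules above, so
# the two paths cross-check each other in tests.

score_tte_matrix <- function(ta, ea, tb, eb, tau, lower_better = FALSE,
                             censoring = "gehan") {
  if (any(ta < 0) || any(tb < 0)) rlang::abort("times must be non-negative")
  n_a <- length(ta); n_b <- length(tb)
  d <- outer(ta, tb, "-")
  EA <- matrix(ea, n_a, n_b)
  EB <- matrix(eb, n_a, n_b, byrow = TRUE)
  a_wins <- EB & d >= tau & d > 0
  b_wins <- EA & -d >= tau & d < 0
  out <- matrix(.VERDICT_UNINF, n_a, n_b)
  out[EA & EB] <- .VERDICT_NEUTRAL
  if (lower_better) {
    # both observed event-free: no difference, not a censoring ambiguity
    out[!EA & !EB] <- .VERDICT_NEUTRAL
  }
  if (censoring == "neutral") {
    out[!(EA & EB)] <- .VERDICT_NEUTRAL
    a_wins <- a_wins & EA & EB
    b_wins <- b_wins & EA & EB
  }
  out[a_wins] <- .VERDICT_A
  out[b_wins] <- .VERDICT_B
  out
}

score_binary_matrix <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  A <- matrix(a, n_a, n_b)
  B <- matrix(b, n_a, n_b, byrow = TRUE)
  out <- matrix(.VERDICT_NEUTRAL, n_a, n_b)
  out[A & !B] <- .VERDICT_A
  out[!A & B] <- .VERDICT_B
  out[is.na(A) | is.na(B)] <- .VERDICT_UNINF
  out
}

score_ordinal_matrix <- function(a, b, direction) {
  d <- outer(a, b, "-")
  if (direction == "lower_better") d <- -d
  out <- matrix(.VERDICT_NEUTRAL, nrow(d), ncol(d))
  out[d > 0] <- .VERDICT_A
  out[d < 0] <- .VERDICT_B
  out[is.na(d)] <- .VERDICT_UNINF
  out
}
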