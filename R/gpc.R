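#' Prepare the per-patient analysis table for the GPC engine
#'
#' Resolves every endpoint of the hierarchy to columns of a single patient
#' table. Two derived columns are added when the hierarchy references them:
#' `qol_global_change`, the change in the transformed QLQ-C30 global-health
#' score from baseline to the latest eligible follow-up (>= 24 months; `NA`,
#' hence uninformative at that level, when no eligible pair exists), and
#' `tox_max_grade`, the per-patient maximum CTCAE grade over follow-up
#' (0 when no toxicity was reported).
#'
#' @param cohort A `gpc_cohort`.
#' @param h A `gpc_hierarchy`.
#' @param scales Scale definitions used to resolve QoL-derived columns.
#' @param min_month Earliest eligible QoL follow-up month.
#' @return The patient tibble with any derived columns appended.
#' @export
prepare_gpc_data <- function(cohort, h = cao_aro_aio12_hierarchy(),
                             scales = eortc_scales(), min_month = 24) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  p <- cohort$patients
  needed <- stats::na.omit(c(h$time_col, h$event_col, h$value_col))
  if ("qol_global_change" %in% needed && !"qol_global_change" %in% names(p)) {
    gh <- scales[scales$scale_id == "global_health", ]
    if (nrow(gh) != 1) rlang::abort("scale definitions lack 'global_health'")
    elig <- eligible_followup(cohort, gh, min_month = min_month)
    p <- p |>
      dplyr::left_join(
        dplyr::transmute(elig, .data$patient_id,
                         qol_global_change = .data$followup_score - .data$baseline_score),
        by = "patient_id"
      )
  }
  if ("tox_max_grade" %in% needed && !"tox_max_grade" %in% names(p)) {
    mx <- max_toxicity_grade(cohort)
    p <- dplyr::left_join(p, dplyr::rename(mx, tox_max_grade = "max_grade"),
                          by = "patient_id")
  }
  missing_cols <- setdiff(needed, names(p))
  if (length(missing_cols) > 0) {
    bad <- h$name[!is.na(h$value_col) & h$value_col %in% missing_cols |
                    !is.na(h$time_col) & h$time_col %in% missing_cols |
                    !is.na(h$event_col) & h$event_col %in% missing_cols]
    rlang::abort(sprintf(
      "endpoint(s) %s reference column(s) absent from the cohort: %s",
      paste(unique(bad), collapse = ", "), paste(missing_cols, collapse = ", ")))
  }
  p
}

# one verdict-code matrix per hierarchy level, comparing every patient of
# `data` in the A role (rows) against every patient in the B role (columns)
score_matrices <- function(data, h, censoring = "gehan") {
  purrr::map(seq_len(nrow(h)), function(i) {
    s <- h[i, ]
    switch(s$kind,
      survival = score_tte_matrix(
        data[[s$time_col]], data[[s$event_col]],
        data[[s$time_col]], data[[s$event_col]],
        tau = s$margin, lower_better = FALSE, censoring = censoring),
      incidence = score_tte_matrix(
        data[[s$time_col]], data[[s$event_col]],
        data[[s$time_col]], data[[s$event_col]],
        tau = s$margin, lower_better = TRUE, censoring = censoring),
      binary = score_binary_matrix(as.logical(data[[s$value_col]]),
                                   as.logical(data[[s$value_col]])),
      ordinal = score_ordinal_matrix(as.numeric(data[[s$value_col]]),
                                     as.numeric(data[[s$value_col]]),
                                     direction = s$direction)
    )
  })
}

# cascade the verdict matrices over (idx_a, idx_b) sub-blocks
gpc_from_matrices <- function(mats, idx_a, idx_b, h) {
  n_pairs <- length(idx_a) * length(idx_b)
  undecided <- rep(TRUE, n_pairs)
  levels <- purrr::map_dfr(seq_along(mats), function(l) {
    v <- mats[[l]][idx_a, idx_b, drop = FALSE]
    reach <- sum(undecided)
    a <- v == .VERDICT_A & undecided
    b <- v == .VERDICT_B & undecided
    out <- tibble::tibble(
      rank = l, name = h$name[l], reaching = reach,
      a_wins = sum(a), b_wins = sum(b),
      neutral = sum(v == .VERDICT_NEUTRAL & undecided),
      uninformative = sum(v == .VERDICT_UNINF & undecided)
    )
    undecided[a | b] <<- FALSE
    out
  })
  list(levels = levels, n_pairs = n_pairs,
       total_a_wins = sum(levels$a_wins), total_b_wins = sum(levels$b_wins))
}

new_gpc_result <- function(core, h, arms, censoring) {
  ntb <- (core$total_b_wins - core$total_a_wins) / core$n_pairs
  structure(list(
    levels = dplyr::mutate(core$levels,
      delta = (.data$b_wins - .data$a_wins) / core$n_pairs),
    n_pairs = core$n_pairs,
    total_a_wins = core$total_a_wins,
    total_b_wins = core$total_b_wins,
    final_ties = core$n_pairs - core$total_a_wins - core$total_b_wins,
    p_better_a = core$total_a_wins / core$n_pairs,
    p_better_b = core$total_b_wins / core$n_pairs,
    ntb = ntb,
    win_ratio = if (core$total_a_wins > 0) core$total_b_wins / core$total_a_wins else Inf,
    hierarchy = h, arms = arms, censoring = censoring
  ), class = "gpc_result")
}

#' Run the prioritized generalized pairwise comparison
#'
#' Compares every arm-A patient with every arm-B patient (`n_A x n_B` ordered
#' pairs, evaluated deterministically) on the ranked endpoint hierarchy.
#' Each pair is decided at the first level at which one patient wins; pairs
#' that are neutral or uninformative at a level cascade to the next, and
#' pairs undecided after the last level are final ties. The net treatment
#' benefit is the probability that a random arm-B patient fares better than a
#' random arm-A patient minus the reverse probability,
#' `(B_wins - A_wins) / n_pairs`; the win ratio is the ratio of total
#' winners, arm B over arm A by default.
#'
#' @param cohort A `gpc_cohort` with both arms non-empty, or a prepared
#'   patient tibble from [prepare_gpc_data()].
#' @param h A `gpc_hierarchy` (default [cao_aro_aio12_hierarchy()]).
#' @param censoring `"gehan"` (default) or `"neutral"`: how pairs involving
#'   censored time-to-event observations are scored; see [compare_survival()].
#' @param scales,min_month Passed to [prepare_gpc_data()] when `cohort` is a
#'   `gpc_cohort`.
#' @return A `gpc_result`: per-level counts and delta contributions, totals,
#'   net treatment benefit, win probabilities and win ratio. Methods:
#'   `print()`, `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' ph <- hierarchy(endpoint_spec("remission", "binary", value_col = "remission"))
#' pts <- tibble::tibble(
#'   patient_id = as.character(1:8), arm = rep(c("A", "B"), each = 4),
#'   remission = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
#' )
#' run_gpc(pts, ph)
#' @export
run_gpc <- function(cohort, h = cao_aro_aio12_hierarchy(),
                    censoring = c("gehan", "neutral"),
                    scales = eortc_scales(), min_month = 24) {
  censoring <- match.arg(censoring)
  data <- if (inherits(cohort, "gpc_cohort")) {
    prepare_gpc_data(cohort, h, scales = scales, min_month = min_month)
  } else {
    tibble::as_tibble(cohort)
  }
  idx_a <- which(data$arm == "A")
  idx_b <- which(data$arm == "B")
  if (length(idx_a) == 0 || length(idx_b) == 0) {
    rlang::abort("both arms must be non-empty")
  }
  mats <- score_matrices(data, h, censoring = censoring)
  core <- gpc_from_matrices(mats, idx_a, idx_b, h)
  new_gpc_result(core, h, arms = c(A = length(idx_a), B = length(idx_b)),
                 censoring = censoring)
}

#' Standalone per-endpoint GPC delta
#'
#' Runs a one-level GPC for a single endpoint, as used for the per-endpoint
#' effect estimates reported alongside the prioritized analysis. For a binary
#' endpoint with no missing values the delta equals the difference in
#' response proportions, `p_B - p_A`, exactly.
#'
#' @inheritParams run_gpc
#' @param spec A one-row endpoint specification from [endpoint_spec()].
#' @return A `gpc_result` with a single level.
#' @export
per_endpoint_delta <- function(cohort, spec, censoring = c("gehan", "neutral"),
                               scales = eortc_scales(), min_month = 24) {
  run_gpc(cohort, hierarchy(spec), censoring = censoring,
          scales = scales, min_month = min_month)
}

#' Level-wise win probabilities, marginal and conditional
#'
#' For each hierarchy level, reports the wins of either arm at that level as
#' a fraction of all pairs (marginal) and as a fraction of the pairs still
#' undecided when the level is reached (conditional). The conditional view
#' answers questions of the form "among pairs with the same long-term
#' outcome, how often does consolidation still win on remission?"; both
#' denominators are emitted because published summaries do not always state
#' which one they use.
#'
#' @param r A `gpc_result`.
#' @return A tibble with one row per level: counts, `reaching`, marginal
#'   (`a_of_all`, `b_of_all`) and conditional (`a_of_reaching`,
#'   `b_of_reaching`) win fractions, and `no_pairs_reached` flagging levels
#'   that no undecided pair reached.
#' @export
decompose_conditional <- function(r) {
  stopifnot(inherits(r, "gpc_result"))
  r$levels |>
    dplyr::mutate(
      a_of_all = .data$a_wins / r$n_pairs,
      b_of_all = .data$b_wins / r$n_pairs,
      a_of_reaching = ifelse(.data$reaching > 0, .data$a_wins / .data$reaching, 0),
      b_of_reaching = ifelse(.data$reaching > 0, .data$b_wins / .data$reaching, 0),
      no_pairs_reached = .data$reaching == 0
    )
}

#' Win ratio of a GPC result
#'
#' Total number of winners of the reference arm divided by the total number
#' of winners of the other arm; 1 under no treatment effect. When the
#' comparator has zero winners the ratio is reported as `Inf` with a warning.
#'
#' @param r A `gpc_result`.
#' @param reference `"B"` (default, matching a consolidation-vs-induction
#'   contrast reported for arm B) or `"A"`.
#' @return A single number.
#' @export
win_ratio <- function(r, reference = c("B", "A")) {
  stopifnot(inherits(r, "gpc_result"))
  reference <- match.arg(reference)
  num <- if (reference == "B") r$total_b_wins else r$total_a_wins
  den <- if (reference == "B") r$total_a_wins else r$total_b_wins
  if (den == 0) {
    rlang::warn("comparator arm has zero winners; win ratio is infinite")
    return(Inf)
  }
  num / den
}

#' @export
print.gpc_result <- function(x, ...) {
  cat(sprintf("<gpc_result> %d x %d patients, %d pairs, scoring: %s\n",
              x$arms[["A"]], x$arms[["B"]], x$n_pairs, x$censoring))
  lv <- x$levels
  for (i in seq_len(nrow(lv))) {
    cat(sprintf("  %d. %-24s A wins %6d  B wins %6d  neutral %6d  uninf %6d\n",
                lv$rank[i], lv$name[i], lv$a_wins[i], lv$b_wins[i],
                lv$neutral[i], lv$uninformative[i]))
  }
  cat(sprintf("  P(better | B) = %.2f%%  P(better | A) = %.2f%%  final ties %d\n",
              100 * x$p_better_b, 100 * x$p_better_a, x$final_ties))
  cat(sprintf("  net treatment benefit %.4f  win ratio (B/A) %.2f\n",
              x$ntb, x$win_ratio))
  invisible(x)
}

#' Tidy a GPC result
#'
#' @param x A `gpc_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per hierarchy level with win/neutral/
#'   uninformative counts, pairs reaching the level, and the level's delta
#'   contribution (contributions sum to the net treatment benefit).
#'   `glance()`: a one-row summary with `n_pairs`, totals, `ntb`,
#'   `win_ratio` and win probabilities.
#' @method tidy gpc_result
#' @export
tidy.gpc_result <- function(x, ...) x$levels

#' @rdname tidy.gpc_result
#' @method glance gpc_result
#' @export
glance.gpc_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, total_a_wins = x$total_a_wins,
    total_b_wins = x$total_b_wins, final_ties = x$final_ties,
    p_better_a = x$p_better_a, p_better_b = x$p_better_b,
    ntb = x$ntb, win_ratio = x$win_ratio
  )
}

#' Plot the per-level decomposition of a GPC result
#'
#' Stacked horizontal bars of pair verdicts (arm-A wins, arm-B wins, neutral,
#' uninformative) at each hierarchy level, among the pairs reaching it.
#'
#' @param object A `gpc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gpc_result
#' @export
autoplot.gpc_result <- function(object, ...) {
  long <- object$levels |>
    dplyr::mutate(level = stats::reorder(.data$name, -.data$rank)) |>
    tidyr::pivot_longer(c("a_wins", "b_wins", "neutral", "uninformative"),
                        names_to = "verdict", values_to = "pairs") |>
    dplyr::mutate(verdict = factor(.data$verdict,
      levels = c("a_wins", "b_wins", "neutral", "uninformative"),
      labels = c("arm A wins", "arm B wins", "neutral", "uninformative")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pairs, y = .data$level,
                                     fill = .data$verdict)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "patient pairs", y = NULL, fill = NULL,
                  title = "Prioritized pairwise comparison by endpoint level") +
    ggplot2::theme_minimal()
}
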