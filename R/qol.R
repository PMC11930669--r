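#' EORTC scale definitions
#'
#' Loads scale definitions (item lists, response-scale range, polarity) for
#' the QLQ-C30 and QLQ-CR29 questionnaires from a JSON definition file. The
#' shipped default covers the standard C30 scales plus the CR29 scales used
#' in long-term colorectal follow-up reporting; item numbering follows the
#' usual convention of appending CR29 items (31-59) after the 30 core items.
#'
#' Polarity drives both the linear transformation and the interpretation of
#' change: for `"functional"` scales a higher transformed score is better and
#' the raw-to-score mapping is reversed; for `"symptom"` scales a higher
#' score means a worse symptom burden; `"global"` is the two-item global
#' health scale (7-point response scale, higher better).
#'
#' @param path JSON file of scale blocks; default is the shipped definition.
#' @return A tibble with columns `scale_id`, `questionnaire`, `items`
#'   (list-column of item numbers), `range`, `polarity`.
#' @export
eortc_scales <- function(path = system.file("extdata", "eortc_scales.json",
                                            package = "netbenefit")) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  purrr::map_dfr(raw, function(x) {
    tibble::tibble(
      scale_id = x$scale_id, questionnaire = x$questionnaire,
      items = list(as.integer(unlist(x$items))),
      range = as.numeric(x$range), polarity = x$polarity
    )
  })
}

#' Linear transformation of raw EORTC items to a 0-100 score
#'
#' Computes the raw score `RS` as the mean of the scale's item responses and
#' applies the standard linear transformation: functional scales score
#' `(1 - (RS - 1) / range) * 100` (so the best functioning maps to 100),
#' symptom and global scales score `((RS - 1) / range) * 100`. A scale is
#' only scored when *all* of its items were answered; any missing item yields
#' `NA` (the patient is excluded for that scale, not an error).
#'
#' @param responses Numeric vector of raw item responses for the scale's
#'   items (order irrelevant), `NA` for unanswered.
#' @param range Difference between the maximum and minimum of the item
#'   response scale (3 for 1-4 items, 6 for the 1-7 global items).
#' @param polarity `"functional"`, `"symptom"` or `"global"`.
#' @param n_items Expected number of items; defaults to `length(responses)`.
#' @return A score in \[0, 100\], or `NA_real_` if any item is missing.
#' @examples
#' transform_scale(c(7, 7), range = 6, polarity = "global")    # 100
#' transform_scale(c(2, 2), range = 3, polarity = "functional") # 66.67
#' @export
transform_scale <- function(responses, range,
                            polarity = c("functional", "symptom", "global"),
                            n_items = length(responses)) {
  polarity <- match.arg(polarity)
  if (range < 1) rlang::abort("`range` must be >= 1")
  if (length(responses) != n_items || anyNA(responses)) return(NA_real_)
  rs <- mean(responses)
  frac <- (rs - 1) / range
  if (polarity == "functional") (1 - frac) * 100 else frac * 100
}

#' Classify a change in a transformed QoL score
#'
#' Any nonzero change counts (no minimally-important-difference threshold):
#' for symptom scales an increase is `"worsened"`, for functional and global
#' scales an increase is `"improved"`; a change of exactly zero is
#' `"neutral"`; a missing change is `"missing"`.
#'
#' @param change Numeric vector of follow-up minus baseline score.
#' @param polarity `"functional"`, `"symptom"` or `"global"` (recycled).
#' @return Character vector of labels.
#' @export
classify_change <- function(change, polarity) {
  # symptom: + is worse; functional/global: + is better
  mult <- rep_len(ifelse(polarity == "symptom", -1, 1), length(change))
  sgn <- sign(change) * mult
  dplyr::case_when(
    is.na(change) ~ "missing",
    sgn > 0 ~ "improved",
    sgn < 0 ~ "worsened",
    TRUE ~ "neutral"
  )
}

# score every (patient, visit) for one scale; NA when any item missing
scale_scores_by_visit <- function(qol, scale_row) {
  items <- scale_row$items[[1]]
  qol |>
    dplyr::filter(.data$questionnaire == scale_row$questionnaire,
                  .data$item %in% items) |>
    dplyr::group_by(.data$patient_id, .data$visit_month) |>
    dplyr::summarise(
      score = transform_scale(.data$response[!duplicated(.data$item)],
                              range = scale_row$range,
                              polarity = scale_row$polarity,
                              n_items = length(items)),
      .groups = "drop"
    )
}

#' Select the eligible follow-up visit for a scale
#'
#' A patient contributes a change score for a scale only when the scale is
#' completely answered at baseline (visit month 0) *and* at a follow-up visit
#' at least `min_month` months after randomization; among complete follow-up
#' visits the latest is used. Patients failing either condition are reported
#' as missing.
#'
#' @param cohort A `gpc_cohort`.
#' @param scale One row of [eortc_scales()].
#' @param min_month Earliest eligible follow-up month (default 24).
#' @return A tibble with one row per patient that has an eligible pair:
#'   `patient_id`, `baseline_score`, `followup_score`, `followup_month`.
#' @export
eligible_followup <- function(cohort, scale, min_month = 24) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  scores <- scale_scores_by_visit(cohort$qol, scale)
  base <- scores |>
    dplyr::filter(.data$visit_month == 0, !is.na(.data$score)) |>
    dplyr::select("patient_id", baseline_score = "score")
  fup <- scores |>
    dplyr::filter(.data$visit_month >= min_month, !is.na(.data$score)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$visit_month, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", followup_score = "score",
                  followup_month = "visit_month")
  dplyr::inner_join(base, fup, by = "patient_id")
}

#' Change-from-baseline scores for a set of scales
#'
#' Applies [eligible_followup()] to each scale and labels the change with
#' [classify_change()]. Patients with no eligible baseline/follow-up pair get
#' an `NA` change and the label `"missing"`.
#'
#' @param cohort A `gpc_cohort`.
#' @param scales Tibble of scale definitions ([eortc_scales()] or a subset).
#' @param min_month Earliest eligible follow-up month (default 24).
#' @return A tibble with one row per (patient, scale): `patient_id`, `arm`,
#'   `sex`, `scale_id`, `polarity`, `baseline_score`, `followup_score`,
#'   `followup_month`, `change`, `label`.
#' @export
qol_changes <- function(cohort, scales = eortc_scales(), min_month = 24) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  per_scale <- purrr::map_dfr(seq_len(nrow(scales)), function(i) {
    row <- scales[i, ]
    eligible_followup(cohort, row, min_month = min_month) |>
      dplyr::mutate(scale_id = row$scale_id)
  })
  if (nrow(per_scale) == 0) {
    per_scale <- tibble::tibble(
      patient_id = character(), baseline_score = numeric(),
      followup_score = numeric(), followup_month = numeric(),
      scale_id = character()
    )
  }
  grid <- tidyr::expand_grid(
    patient_id = cohort$patients$patient_id,
    scale_id = scales$scale_id
  )
  grid |>
    dplyr::left_join(dplyr::select(scales, "scale_id", "polarity"), by = "scale_id") |>
    dplyr::left_join(per_scale, by = c("patient_id", "scale_id")) |>
    dplyr::left_join(
      dplyr::select(cohort$patients, "patient_id", "arm", "sex"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      change = .data$followup_score - .data$baseline_score,
      label = classify_change(.data$change, .data$polarity)
    ) |>
    dplyr::select("patient_id", "arm", "sex", "scale_id", "polarity",
                  "baseline_score", "followup_score", "followup_month",
                  "change", "label")
}

#' Per-scale, per-sex QoL change table with between-arm t-tests
#'
#' For every scale and sex, counts patients whose transformed score worsened
#' (`negative`), did not change (`neutral`) or improved (`positive`) between
#' baseline and the latest eligible follow-up, per arm, with percentages over
#' the non-missing patients of that sex and arm, plus a two-sided two-sample
#' t-test comparing the raw change scores between arms (Welch by default;
#' `pooled = TRUE` gives the equal-variance test). P-values are unadjusted
#' for multiplicity. Cells with fewer than two non-missing patients in either
#' arm, or with zero variance in both arms, report `NA`.
#'
#' @param cohort A `gpc_cohort`.
#' @param scales Scale definitions; default all shipped scales.
#' @param min_month Earliest eligible follow-up month (default 24).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A tibble with one row per (scale, sex): missing/negative/neutral/
#'   positive counts and percentages per arm, `t_stat` and `p_value`.
#' @export
qol_change_table <- function(cohort, scales = eortc_scales(), min_month = 24,
                             pooled = FALSE) {
  ch <- qol_changes(cohort, scales, min_month = min_month)
  counts <- ch |>
    dplyr::group_by(.data$scale_id, .data$sex, .data$arm) |>
    dplyr::summarise(
      missing = sum(.data$label == "missing"),
      negative = sum(.data$label == "worsened"),
      neutral = sum(.data$label == "neutral"),
      positive = sum(.data$label == "improved"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      nonmiss = .data$negative + .data$neutral + .data$positive,
      negative_pct = pct_of(.data$negative, .data$nonmiss),
      neutral_pct = pct_of(.data$neutral, .data$nonmiss),
      positive_pct = pct_of(.data$positive, .data$nonmiss)
    ) |>
    tidyr::pivot_wider(
      names_from = "arm",
      values_from = c("missing", "negative", "neutral", "positive", "nonmiss",
                      "negative_pct", "neutral_pct", "positive_pct"),
      names_sep = "_"
    )
  tests <- ch |>
    dplyr::group_by(.data$scale_id, .data$sex) |>
    dplyr::summarise(
      res = list(welch_change_test(.data$change[.data$arm == "A"],
                                   .data$change[.data$arm == "B"],
                                   pooled = pooled)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
  out <- dplyr::left_join(counts, tests, by = c("scale_id", "sex"))
  dplyr::arrange(out, match(.data$scale_id, scales$scale_id), .data$sex)
}

pct_of <- function(n, denom) {
  ifelse(denom > 0, as.integer(round(100 * n / denom)), NA_integer_)
}

welch_change_test <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2 ||
      (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    return(list(t_stat = NA_real_, p_value = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value)
}
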