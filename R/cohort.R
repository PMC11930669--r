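#' Build a two-arm trial cohort
#'
#' A cohort bundles one row per patient with long-format companion tables for
#' follow-up toxicity visits and quality-of-life questionnaire responses.
#'
#' @param patients Tibble with columns `patient_id` (unique strings), `arm`
#'   (`"A"`/`"B"`), `sex` (`"male"`/`"female"`), `os_time`, `os_event`,
#'   `lr_time`, `lr_event`, `dm_time`, `dm_event` (times in months >= 0,
#'   events logical), `remission` (logical, `NA` allowed).
#' @param tox Tibble with columns `patient_id`, `visit_month`, `item`,
#'   `grade` (CTCAE grade 1-4). Patients absent from this table have grade 0
#'   by convention. May be empty.
#' @param qol Tibble with columns `patient_id`, `visit_month` (0 = baseline),
#'   `questionnaire` (`"C30"`/`"CR29"`), `item` (item number), `response`
#'   (integer on the item's response scale). May be empty.
#' @param label Optional cohort label.
#' @return An object of class `gpc_cohort`.
#' @seealso [read_cohort()], [simulate_cohort()]
#' @export
gpc_cohort <- function(patients, tox = empty_tox(), qol = empty_qol(),
                       label = "cohort") {
  patients <- tibble::as_tibble(patients)
  tox <- tibble::as_tibble(tox)
  qol <- tibble::as_tibble(qol)
  x <- structure(
    list(patients = patients, tox = tox, qol = qol, label = label),
    class = "gpc_cohort"
  )
  validate_cohort(x)
}

empty_tox <- function() {
  tibble::tibble(patient_id = character(), visit_month = numeric(),
                 item = character(), grade = integer())
}

empty_qol <- function() {
  tibble::tibble(patient_id = character(), visit_month = numeric(),
                 questionnaire = character(), item = integer(),
                 response = integer())
}

patient_cols <- c("patient_id", "arm", "sex", "os_time", "os_event",
                  "lr_time", "lr_event", "dm_time", "dm_event", "remission")

#' Validate a cohort
#'
#' Checks column presence, types, uniqueness of patient ids, valid arms and
#' sexes, non-negative finite times, logical event flags, toxicity grades in
#' 1-4, and that companion tables refer only to known patients. Errors name
#' the offending rows.
#'
#' @param x A `gpc_cohort`.
#' @return `x`, invisibly usable in a pipe.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "gpc_cohort"))
  p <- x$patients
  missing_cols <- setdiff(patient_cols, names(p))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("patient table is missing mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      rlang::abort(sprintf("%s in patient row(s): %s", what,
                           paste(utils::head(idx, 5), collapse = ", ")))
    }
  }
  if (anyDuplicated(p$patient_id)) {
    rlang::abort("patient_id values must be unique")
  }
  bad_row(!p$arm %in% c("A", "B"), "arm must be 'A' or 'B'")
  bad_row(!p$sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  for (tc in c("os_time", "lr_time", "dm_time")) {
    if (!is.numeric(p[[tc]])) {
      rlang::abort(sprintf("column %s must be numeric (months)", tc))
    }
    bad_row(!is.finite(p[[tc]]) | p[[tc]] < 0,
            sprintf("%s must be finite and >= 0", tc))
  }
  for (ec in c("os_event", "lr_event", "dm_event")) {
    if (!is.logical(p[[ec]])) {
      rlang::abort(sprintf("column %s must be logical", ec))
    }
    bad_row(is.na(p[[ec]]), sprintf("%s must not be missing", ec))
  }
  if (!is.logical(p$remission)) rlang::abort("remission must be logical (NA allowed)")
  if (nrow(x$tox) > 0) {
    bad <- which(!x$tox$grade %in% 1:4)
    if (length(bad) > 0) {
      rlang::abort(sprintf("toxicity grades must be in 1..4; bad row(s): %s",
                           paste(utils::head(bad, 5), collapse = ", ")))
    }
    unknown <- setdiff(x$tox$patient_id, p$patient_id)
    if (length(unknown) > 0) {
      rlang::abort(sprintf("toxicity table refers to unknown patient(s): %s",
                           paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  if (nrow(x$qol) > 0) {
    unknown <- setdiff(x$qol$patient_id, p$patient_id)
    if (length(unknown) > 0) {
      rlang::abort(sprintf("QoL table refers to unknown patient(s): %s",
                           paste(utils::head(unknown, 5), collapse = ", ")))
    }
    bad <- which(!x$qol$questionnaire %in% c("C30", "CR29"))
    if (length(bad) > 0) {
      rlang::abort(sprintf("questionnaire must be 'C30' or 'CR29'; bad row(s): %s",
                           paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
print.gpc_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<gpc_cohort> %s: %d patients (arm A %d, arm B %d)\n",
              x$label, nrow(p), sum(p$arm == "A"), sum(p$arm == "B")))
  cat(sprintf("  toxicity visits: %d rows; QoL responses: %d rows\n",
              nrow(x$tox), nrow(x$qol)))
  invisible(x)
}

#' Read / write a cohort as delimited files
#'
#' A cohort on disk is a directory with three UTF-8 delimited files:
#' `patients.csv` (one row per patient), `toxicity.csv` and `qol.csv`
#' (long-format companion tables). The delimiter is configurable and the
#' round trip `read_cohort(write_cohort(x))` is lossless.
#'
#' @param dir Directory containing (or to receive) the three files.
#' @param delim Field delimiter (default comma).
#' @param label Cohort label; defaults to the directory name.
#' @return `read_cohort()` returns a validated [gpc_cohort()];
#'   `write_cohort()` returns `dir` invisibly.
#' @export
read_cohort <- function(dir, delim = ",", label = basename(dir)) {
  pfile <- file.path(dir, "patients.csv")
  if (!file.exists(pfile)) {
    rlang::abort(sprintf("cohort file not found: %s", pfile))
  }
  spec_p <- readr::cols(
    patient_id = readr::col_character(), arm = readr::col_character(),
    sex = readr::col_character(), os_time = readr::col_double(),
    os_event = readr::col_logical(), lr_time = readr::col_double(),
    lr_event = readr::col_logical(), dm_time = readr::col_double(),
    dm_event = readr::col_logical(), remission = readr::col_logical()
  )
  p <- readr::read_delim(pfile, delim = delim, col_types = spec_p,
                         na = c("", "NA"), progress = FALSE)
  prob <- readr::problems(p)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf(
      "parse error in %s, row %d, column %s: expected %s, got '%s'",
      pfile, prob$row[1], prob$col[1], prob$expected[1], prob$actual[1]))
  }
  tfile <- file.path(dir, "toxicity.csv")
  tox <- if (file.exists(tfile)) {
    readr::read_delim(tfile, delim = delim, progress = FALSE,
                      col_types = readr::cols(
                        patient_id = readr::col_character(),
                        visit_month = readr::col_double(),
                        item = readr::col_character(),
                        grade = readr::col_integer()))
  } else {
    empty_tox()
  }
  qfile <- file.path(dir, "qol.csv")
  qol <- if (file.exists(qfile)) {
    readr::read_delim(qfile, delim = delim, progress = FALSE,
                      col_types = readr::cols(
                        patient_id = readr::col_character(),
                        visit_month = readr::col_double(),
                        questionnaire = readr::col_character(),
                        item = readr::col_integer(),
                        response = readr::col_integer()))
  } else {
    empty_qol()
  }
  gpc_cohort(p, tox, qol, label = label)
}

#' @rdname read_cohort
#' @param x A `gpc_cohort`.
#' @export
write_cohort <- function(x, dir, delim = ",") {
  stopifnot(inherits(x, "gpc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_delim(x$patients, file.path(dir, "patients.csv"), delim = delim)
  readr::write_delim(x$tox, file.path(dir, "toxicity.csv"), delim = delim)
  readr::write_delim(x$qol, file.path(dir, "qol.csv"), delim = delim)
  invisible(dir)
}

#' Per-patient maximum toxicity grade
#'
#' The maximum CTCAE grade over all follow-up toxicity visits, optionally
#' restricted to a time window; patients with no (in-window) visit have
#' grade 0 by convention.
#'
#' @param cohort A `gpc_cohort`.
#' @param window Optional `c(start, end)` window in months (inclusive).
#' @return A tibble with one row per patient: `patient_id`, `max_grade`.
#' @export
max_toxicity_grade <- function(cohort, window = NULL) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  tox <- cohort$tox
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] > window[2]) {
      rlang::abort("`window` must be c(start, end) with start <= end")
    }
    tox <- dplyr::filter(tox, .data$visit_month >= window[1],
                         .data$visit_month <= window[2])
  }
  mx <- if (nrow(tox) == 0) {
    tibble::tibble(patient_id = character(), max_grade = integer())
  } else {
    tox |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(max_grade = max(.data$grade), .groups = "drop")
  }
  cohort$patients |>
    dplyr::select("patient_id") |>
    dplyr::left_join(mx, by = "patient_id") |>
    dplyr::mutate(max_grade = as.integer(dplyr::coalesce(.data$max_grade, 0L)))
}

#' Follow-up toxicity table by item, grade and arm
#'
#' Reproduces the structure of a per-period toxicity table: for every
#' toxicity item and arm, the number of patients whose *maximum* grade for
#' that item over follow-up was 1, 2, 3 or 4, the any-grade (>= 1) and
#' high-grade (>= 3) counts, percentages of the arm's size rounded to the
#' nearest integer, and arm-B-minus-arm-A differences of the rounded
#' percentages. A synthetic `"highest_per_patient"` row summarises each
#' patient's maximum grade over all items.
#'
#' @param cohort A `gpc_cohort`.
#' @return A tibble with one row per toxicity item (plus the overall row) and
#'   columns `item`, then per arm `g1..g4`, `any_n`, `any_pct`, `high_n`,
#'   `high_pct` (suffixed `_A`/`_B`), and `diff_any_pct`, `diff_high_pct`.
#' @export
toxicity_table <- function(cohort) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  p <- cohort$patients
  if (nrow(p) == 0) rlang::abort("cohort is empty")
  n_arm <- c(A = sum(p$arm == "A"), B = sum(p$arm == "B"))

  empty_grades <- tibble::tibble(patient_id = character(), item = character(),
                                 grade = integer())
  per_item <- if (nrow(cohort$tox) == 0) empty_grades else {
    dplyr::summarise(cohort$tox, grade = max(.data$grade),
                     .by = c("patient_id", "item"))
  }
  overall <- if (nrow(per_item) == 0) empty_grades else {
    per_item |>
      dplyr::summarise(grade = max(.data$grade), .by = "patient_id") |>
      dplyr::mutate(item = "highest_per_patient")
  }
  long <- dplyr::bind_rows(per_item, overall) |>
    dplyr::left_join(dplyr::select(p, "patient_id", "arm"), by = "patient_id")

  arm_block <- function(arm_label) {
    n <- n_arm[[arm_label]]
    long |>
      dplyr::filter(.data$arm == arm_label) |>
      dplyr::group_by(.data$item) |>
      dplyr::summarise(
        g1 = sum(.data$grade == 1), g2 = sum(.data$grade == 2),
        g3 = sum(.data$grade == 3), g4 = sum(.data$grade == 4),
        any_n = dplyr::n(), high_n = sum(.data$grade >= 3),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        any_pct = as.integer(round(100 * .data$any_n / n)),
        high_pct = as.integer(round(100 * .data$high_n / n))
      )
  }
  items <- tibble::tibble(item = unique(c(per_item$item, "highest_per_patient")))
  fill0 <- function(df) {
    dplyr::mutate(df, dplyr::across(-"item", \(v) dplyr::coalesce(v, 0L)))
  }
  out <- items |>
    dplyr::left_join(arm_block("A"), by = "item") |>
    fill0() |>
    dplyr::left_join(arm_block("B"), by = "item", suffix = c("_A", "_B")) |>
    fill0()
  # difference columns on the rounded percentages, matching +8/-4 style
  dplyr::mutate(out,
    diff_any_pct = .data$any_pct_B - .data$any_pct_A,
    diff_high_pct = .data$high_pct_B - .data$high_pct_A
  )
}
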