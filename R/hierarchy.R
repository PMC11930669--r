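#' Define one endpoint of a prioritized hierarchy
#'
#' An endpoint specification names the patient-level columns that feed a
#' single level of the generalized pairwise comparison cascade, its kind, the
#' favorable direction, and (for time-to-event kinds) the clinical-relevance
#' margin in months.
#'
#' @param name Endpoint label used in reports.
#' @param kind One of `"survival"` (higher-is-better time-to-event),
#'   `"incidence"` (lower-is-better time-to-event), `"binary"`, `"ordinal"`.
#' @param direction `"higher_better"` or `"lower_better"`. For `"survival"`
#'   this must be `"higher_better"`, for `"incidence"` `"lower_better"`.
#' @param margin Clinical-relevance margin tau in months (time-to-event kinds
#'   only): two events less than `margin` apart count as no difference.
#' @param time_col,event_col Column names in the prepared patient table
#'   holding observed time and event indicator (time-to-event kinds).
#' @param value_col Column name holding the value (binary/ordinal kinds).
#' @return A one-row tibble; rows are stacked by [hierarchy()].
#' @seealso [hierarchy()], [cao_aro_aio12_hierarchy()]
#' @export
endpoint_spec <- function(name, kind = c("survival", "incidence", "binary", "ordinal"),
                          direction = NULL, margin = 0,
                          time_col = NULL, event_col = NULL, value_col = NULL) {
  kind <- match.arg(kind)
  direction <- direction %||% switch(kind,
    survival = "higher_better", incidence = "lower_better",
    binary = "higher_better", ordinal = "higher_better")
  if (!direction %in% c("higher_better", "lower_better")) {
    rlang::abort("`direction` must be 'higher_better' or 'lower_better'")
  }
  if (kind == "survival" && direction != "higher_better") {
    rlang::abort("survival endpoints are higher_better; use kind = 'incidence' for lower-is-better times")
  }
  if (kind == "incidence" && direction != "lower_better") {
    rlang::abort("incidence endpoints are lower_better")
  }
  if (!is.numeric(margin) || length(margin) != 1 || is.na(margin) || margin < 0) {
    rlang::abort("`margin` must be a single non-negative number of months")
  }
  if (kind %in% c("survival", "incidence")) {
    if (is.null(time_col) || is.null(event_col)) {
      rlang::abort(sprintf("endpoint '%s': time-to-event kinds need `time_col` and `event_col`", name))
    }
  } else if (is.null(value_col)) {
    rlang::abort(sprintf("endpoint '%s': '%s' endpoints need `value_col`", name, kind))
  }
  tibble::tibble(
    name = as.character(name), kind = kind, direction = direction,
    margin = as.numeric(margin),
    time_col = time_col %||% NA_character_,
    event_col = event_col %||% NA_character_,
    value_col = value_col %||% NA_character_
  )
}

#' Assemble an ordered endpoint hierarchy
#'
#' Stacks endpoint specifications in priority order (rank 1 is compared
#' first). Ranks are assigned contiguously from 1 in the order given.
#'
#' @param ... One-row tibbles from [endpoint_spec()].
#' @return A tibble of class `gpc_hierarchy`, one row per level.
#' @examples
#' hierarchy(
#'   endpoint_spec("os", "survival", margin = 1, time_col = "os_time", event_col = "os_event"),
#'   endpoint_spec("remission", "binary", value_col = "remission")
#' )
#' @export
hierarchy <- function(...) {
  specs <- rlang::list2(...)
  if (length(specs) == 0) rlang::abort("a hierarchy needs at least one endpoint")
  h <- dplyr::bind_rows(specs)
  if (anyDuplicated(h$name)) rlang::abort("endpoint names must be unique")
  h <- dplyr::mutate(h, rank = dplyr::row_number(), .before = 1)
  class(h) <- c("gpc_hierarchy", class(h))
  h
}

#' The default prioritized hierarchy for the rectal-cancer TNT analysis
#'
#' Six levels in the published priority order: overall survival (margin 1
#' month), locoregional recurrence incidence (1 month), distant metastasis
#' incidence (1 month), pathological/sustained clinical complete remission
#' (binary), change in EORTC QLQ-C30 global health from baseline to the
#' latest follow-up at >= 24 months (ordinal, higher is better), and maximum
#' CTCAE toxicity grade over follow-up (ordinal, lower is better). The QoL
#' and toxicity columns are derived columns added by [prepare_gpc_data()].
#'
#' @return A `gpc_hierarchy` tibble with six rows.
#' @export
cao_aro_aio12_hierarchy <- function() {
  hierarchy(
    endpoint_spec("overall_survival", "survival", margin = 1,
                  time_col = "os_time", event_col = "os_event"),
    endpoint_spec("locoregional_recurrence", "incidence", margin = 1,
                  time_col = "lr_time", event_col = "lr_event"),
    endpoint_spec("distant_metastasis", "incidence", margin = 1,
                  time_col = "dm_time", event_col = "dm_event"),
    endpoint_spec("complete_remission", "binary", value_col = "remission"),
    endpoint_spec("global_health_change", "ordinal", direction = "higher_better",
                  value_col = "qol_global_change"),
    endpoint_spec("max_toxicity_grade", "ordinal", direction = "lower_better",
                  value_col = "tox_max_grade")
  )
}

#' Read or write a hierarchy configuration file
#'
#' The configuration is a JSON array of endpoint blocks with fields `name`,
#' `kind`, `direction`, `margin`, `time_col`/`event_col` or `value_col`,
#' in priority order.
#'
#' @param path File path.
#' @return `read_hierarchy()` returns a `gpc_hierarchy`; `write_hierarchy()`
#'   returns `path` invisibly.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("hierarchy file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  specs <- purrr::map(raw, function(x) {
    endpoint_spec(
      name = x$name, kind = x$kind, direction = x$direction %||% NULL,
      margin = x$margin %||% 0,
      time_col = x$time_col %||% NULL, event_col = x$event_col %||% NULL,
      value_col = x$value_col %||% NULL
    )
  })
  rlang::exec(hierarchy, !!!specs)
}

#' @rdname read_hierarchy
#' @param h A `gpc_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  blocks <- purrr::pmap(h, function(rank, name, kind, direction, margin,
                                    time_col, event_col, value_col) {
    x <- list(name = name, kind = kind, direction = direction, margin = margin)
    if (!is.na(time_col)) x$time_col <- time_col
    if (!is.na(event_col)) x$event_col <- event_col
    if (!is.na(value_col)) x$value_col <- value_col
    x
  })
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
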