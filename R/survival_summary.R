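#' Kaplan-Meier survival probability at a fixed horizon
#'
#' Product-limit estimate of survival at `horizon` months, with an optional
#' Greenwood-variance log-log confidence interval (the usual choice for
#' 5-year survival reporting).
#'
#' @param time Observed times in months (>= 0).
#' @param event Logical event indicators.
#' @param horizon Horizon in months (default 60).
#' @param conf_level Confidence level, or `NULL` for no interval.
#' @return A one-row tibble: `horizon`, `estimate`, `n_at_risk`, `lower`,
#'   `upper`.
#' @export
kaplan_meier <- function(time, event, horizon = 60, conf_level = 0.95) {
  if (length(time) == 0) rlang::abort("no observations")
  if (any(time < 0)) rlang::abort("times must be >= 0")
  fit <- survival::survfit(
    survival::Surv(time, as.integer(event)) ~ 1,
    conf.type = if (is.null(conf_level)) "none" else "log-log",
    conf.int = conf_level %||% 0.95
  )
  s <- summary(fit, times = horizon, extend = TRUE)
  tibble::tibble(
    horizon = horizon, estimate = s$surv, n_at_risk = s$n.risk,
    lower = if (is.null(conf_level)) NA_real_ else s$lower,
    upper = if (is.null(conf_level)) NA_real_ else s$upper
  )
}

#' Cumulative incidence at a fixed horizon under competing risks
#'
#' Aalen-Johansen estimate of the probability of the event of interest by
#' `horizon`, treating death without the event as a competing risk
#' (`method = "aalen-johansen"`, the default). The simpler complement-of-
#' Kaplan-Meier variant, which censors at death, is available as
#' `method = "one-minus-km"` for sensitivity analyses; it is never smaller.
#'
#' @param time Time to first of event/death/censoring, in months.
#' @param status Integer: 0 censored, 1 event of interest, 2 competing death.
#' @param horizon Horizon in months (default 60).
#' @param method `"aalen-johansen"` or `"one-minus-km"`.
#' @param conf_level Confidence level, or `NULL`.
#' @return A one-row tibble: `horizon`, `estimate`, `n_at_risk`, `lower`,
#'   `upper`.
#' @export
cumulative_incidence <- function(time, status, horizon = 60,
                                 method = c("aalen-johansen", "one-minus-km"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  if (length(time) == 0) rlang::abort("no observations")
  if (any(time < 0)) rlang::abort("times must be >= 0")
  if (!all(status %in% 0:2)) rlang::abort("status must be 0 (censor), 1 (event) or 2 (death)")
  if (method == "one-minus-km") {
    km <- kaplan_meier(time, status == 1, horizon = horizon,
                       conf_level = conf_level)
    return(tibble::tibble(
      horizon = horizon, estimate = 1 - km$estimate, n_at_risk = km$n_at_risk,
      lower = 1 - km$upper, upper = 1 - km$lower
    ))
  }
  if (all(status == 0)) {
    # no transitions at all: the multi-state fit degenerates, incidence is 0
    return(tibble::tibble(horizon = horizon, estimate = 0,
                          n_at_risk = sum(time >= horizon),
                          lower = NA_real_, upper = NA_real_))
  }
  st <- factor(status, levels = 0:2, labels = c("censor", "event", "death"))
  fit <- survival::survfit(survival::Surv(time, st) ~ 1,
                           conf.int = conf_level %||% 0.95)
  s <- summary(fit, times = horizon, extend = TRUE)
  col <- which(fit$states == "event")
  tibble::tibble(
    horizon = horizon, estimate = unname(s$pstate[, col]),
    n_at_risk = unname(s$n.risk[, 1]),
    lower = if (is.null(conf_level)) NA_real_ else unname(s$lower[, col]),
    upper = if (is.null(conf_level)) NA_real_ else unname(s$upper[, col])
  )
}

#' Per-arm survival and cumulative-incidence summary at fixed horizons
#'
#' Overall survival by Kaplan-Meier, plus cumulative incidence of
#' locoregional recurrence and distant metastasis with death as a competing
#' risk, per arm, at the requested horizons.
#'
#' @param cohort A `gpc_cohort`.
#' @param horizons Numeric vector of horizons in months (default 60).
#' @param method Cumulative-incidence estimator, see [cumulative_incidence()].
#' @param conf_level Confidence level.
#' @return A tibble with columns `endpoint`, `arm`, `horizon`, `estimate`,
#'   `n_at_risk`, `lower`, `upper`.
#' @export
survival_summary <- function(cohort, horizons = 60,
                             method = c("aalen-johansen", "one-minus-km"),
                             conf_level = 0.95) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  method <- match.arg(method)
  p <- cohort$patients
  one_arm <- function(arm) {
    d <- p[p$arm == arm, ]
    os <- purrr::map_dfr(horizons, function(hz) {
      kaplan_meier(d$os_time, d$os_event, horizon = hz, conf_level = conf_level)
    }) |> dplyr::mutate(endpoint = "overall_survival")
    cif_block <- function(ev_time, ev_event, name) {
      # first of event / death-without-event / censoring
      t1 <- pmin(ev_time, d$os_time)
      status <- dplyr::case_when(
        ev_event & ev_time <= d$os_time ~ 1L,
        d$os_event ~ 2L,
        TRUE ~ 0L
      )
      purrr::map_dfr(horizons, function(hz) {
        cumulative_incidence(t1, status, horizon = hz, method = method,
                             conf_level = conf_level)
      }) |> dplyr::mutate(endpoint = name)
    }
    dplyr::bind_rows(
      os,
      cif_block(d$lr_time, d$lr_event, "locoregional_recurrence"),
      cif_block(d$dm_time, d$dm_event, "distant_metastasis")
    ) |> dplyr::mutate(arm = arm)
  }
  dplyr::bind_rows(one_arm("A"), one_arm("B")) |>
    dplyr::select("endpoint", "arm", "horizon", "estimate", "n_at_risk",
                  "lower", "upper")
}

#' Kaplan-Meier curves by arm
#'
#' @param cohort A `gpc_cohort`.
#' @param ... Unused.
#' @return A ggplot step-curve of overall survival by arm.
#' @export
plot_survival <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gpc_cohort"))
  p <- cohort$patients
  fit <- survival::survfit(
    survival::Surv(os_time, as.integer(os_event)) ~ arm, data = p)
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(
    time = fit$time, surv = fit$surv,
    arm = sub("^arm=", "", strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since randomization", y = "overall survival",
                  colour = "arm") +
    ggplot2::theme_minimal()
}
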