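#' Simulation parameters for a synthetic two-arm TNT cohort
#'
#' The defaults state the world the analysis was reported in: 156/150
#' patients, exponential overall survival calibrated to 5-year rates of
#' 85.8% (arm A) and 84.2% (arm B), 5-year locoregional recurrence
#' probabilities of 6.9%/5.9% and distant metastasis 21.7%/23.76%, complete
#' remission 21%/27%, per-patient administrative follow-up uniform on
#' [58, 62] months (median 60, interquartile range 58-62), 40% of patients
#' without usable follow-up QoL, and per-patient maximum CTCAE grade drawn
#' from the published highest-toxicity-per-patient distribution.
#'
#' @param n_A,n_B Arm sizes.
#' @param os_rate_A,os_rate_B Exponential overall-survival hazards per month.
#' @param lr_prob,dm_prob Named vectors `c(A = , B = )` of 5-year event
#'   probabilities for locoregional recurrence and distant metastasis.
#' @param cr_prob_A,cr_prob_B Complete-remission probabilities.
#' @param accrual_window Spread of per-patient follow-up in months: follow-up
#'   is uniform on `[admin_censor, admin_censor + accrual_window]`.
#' @param admin_censor Minimum administrative follow-up in months.
#' @param qol_missing_prob Probability that a surviving patient lacks a
#'   usable follow-up QoL visit.
#' @param tox_grade_probs List with elements `A` and `B`, each a length-5
#'   probability vector over maximum grades 0-4.
#' @param qol_shift Named vector `c(A = , B = )`: mean change (0-100 score
#'   points) of global health between baseline and follow-up.
#' @param prop_male Proportion of male patients.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(
    n_A = 156, n_B = 150,
    os_rate_A = -log(0.858) / 60, os_rate_B = -log(0.842) / 60,
    lr_prob = c(A = 0.069, B = 0.059),
    dm_prob = c(A = 0.217, B = 0.2376),
    cr_prob_A = 0.21, cr_prob_B = 0.27,
    accrual_window = 4, admin_censor = 58,
    qol_missing_prob = 0.4,
    tox_grade_probs = list(A = c(36, 30, 38, 48, 4) / 156,
                           B = c(35, 33, 33, 45, 4) / 150),
    qol_shift = c(A = 5, B = 5),
    prop_male = 0.7) {
  p <- list(
    n_A = n_A, n_B = n_B, os_rate_A = os_rate_A, os_rate_B = os_rate_B,
    lr_prob = lr_prob, dm_prob = dm_prob,
    cr_prob_A = cr_prob_A, cr_prob_B = cr_prob_B,
    accrual_window = accrual_window, admin_censor = admin_censor,
    qol_missing_prob = qol_missing_prob, tox_grade_probs = tox_grade_probs,
    qol_shift = qol_shift, prop_male = prop_male
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  chk_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      rlang::abort(sprintf("%s must be probabilities in [0, 1]", what))
    }
  }
  if (p$n_A < 1 || p$n_B < 1) rlang::abort("arm sizes must be >= 1")
  if (p$os_rate_A <= 0 || p$os_rate_B <= 0) rlang::abort("hazards must be positive")
  chk_prob(p$lr_prob, "lr_prob"); chk_prob(p$dm_prob, "dm_prob")
  chk_prob(c(p$cr_prob_A, p$cr_prob_B), "cr_prob")
  chk_prob(p$qol_missing_prob, "qol_missing_prob")
  chk_prob(p$prop_male, "prop_male")
  for (arm in c("A", "B")) {
    g <- p$tox_grade_probs[[arm]]
    if (length(g) != 5 || abs(sum(g) - 1) > 1e-8 || any(g < 0)) {
      rlang::abort("tox_grade_probs must be two length-5 distributions over grades 0-4")
    }
  }
  if (p$accrual_window < 0 || p$admin_censor <= 0) {
    rlang::abort("follow-up windows must be positive")
  }
  p
}

#' Read simulation parameters from a JSON file
#'
#' Fields mirror the arguments of [sim_params()]; absent fields keep their
#' defaults.
#'
#' @param path JSON file.
#' @return A `sim_params` object.
#' @export
read_sim_params <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("params file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown simulation parameter(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  raw <- purrr::map(raw, function(x) if (is.list(x)) purrr::map(x, unlist) else unlist(x))
  for (f in c("lr_prob", "dm_prob", "qol_shift")) {
    if (f %in% names(raw)) raw[[f]] <- stats::setNames(as.numeric(raw[[f]]), c("A", "B"))
  }
  rlang::exec(sim_params, !!!raw)
}

# one simulated arm as (patients, tox, qol) tibbles
simulate_arm <- function(n, arm, os_rate, lr_p, dm_p, cr_p, tox_probs,
                         qshift, p) {
  id <- sprintf("%s%03d", arm, seq_len(n))
  fup <- stats::runif(n, p$admin_censor, p$admin_censor + p$accrual_window)
  t_os <- stats::rexp(n, rate = os_rate)
  os_event <- t_os < fup
  os_time <- pmin(t_os, fup)

  gen_tte <- function(prob) {
    ev <- stats::runif(n) < prob
    t_raw <- stats::runif(n, 0, fup)
    # death (or administrative cutoff) truncates observation of the event
    observed <- ev & t_raw <= os_time
    list(time = ifelse(observed, t_raw, os_time), event = observed)
  }
  lr <- gen_tte(lr_p)
  dm <- gen_tte(dm_p)

  patients <- tibble::tibble(
    patient_id = id, arm = arm,
    sex = ifelse(stats::runif(n) < p$prop_male, "male", "female"),
    os_time = os_time, os_event = os_event,
    lr_time = lr$time, lr_event = lr$event,
    dm_time = dm$time, dm_event = dm$event,
    remission = stats::runif(n) < cr_p
  )

  grade <- sample(0:4, n, replace = TRUE, prob = tox_probs)
  has_tox <- grade >= 1
  tox <- tibble::tibble(
    patient_id = id[has_tox],
    visit_month = round(stats::runif(sum(has_tox), 1, pmax(2, os_time[has_tox])), 1),
    item = "overall",
    grade = as.integer(grade[has_tox])
  )

  qol <- simulate_qol(id, os_time, qshift, p)
  list(patients = patients, tox = tox, qol = qol)
}

# QLQ-C30 responses: complete baseline for everyone, one follow-up visit at
# month U(24, 36) for surviving patients not hit by missingness
simulate_qol <- function(id, os_time, qshift, p) {
  n <- length(id)
  fup_month <- round(stats::runif(n, 24, 36), 1)
  has_fup <- os_time >= fup_month & stats::runif(n) >= p$qol_missing_prob

  base14 <- matrix(sample(1:4, n * 28, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1)), n, 28)
  base7 <- matrix(pmin(pmax(round(stats::rnorm(n * 2, 5, 1.2)), 1), 7), n, 2)
  step <- matrix(sample(-1:1, n * 28, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3)), n, 28)
  fup14 <- pmin(pmax(base14 + step, 1), 4)
  # per-patient latent global-health change: qshift points on the 0-100
  # scale is qshift * 6 / 100 raw points on the 1-7 items
  drift <- stats::rnorm(n, qshift * 6 / 100, 1)
  fup7 <- pmin(pmax(round(base7 + drift), 1), 7)

  block <- function(mat, months, items) {
    tibble::tibble(
      patient_id = rep(id, times = length(items)),
      visit_month = rep(months, times = length(items)),
      questionnaire = "C30",
      item = rep(items, each = n),
      response = as.integer(mat)
    )
  }
  baseline <- dplyr::bind_rows(
    block(base14, rep(0, n), 1:28),
    block(base7, rep(0, n), 29:30)
  )
  followup <- dplyr::bind_rows(
    block(fup14, fup_month, 1:28),
    block(fup7, fup_month, 29:30)
  ) |>
    dplyr::filter(rep(has_fup, times = 30))
  dplyr::bind_rows(baseline, followup) |>
    dplyr::arrange(.data$patient_id, .data$visit_month, .data$item)
}

#' Generate a synthetic two-arm cohort
#'
#' Draws a cohort from the stated simulation world: exponential overall
#' survival with administrative censoring, marginal Bernoulli locoregional
#' recurrence and distant metastasis with event times uniform over follow-up
#' (death truncates their observation), Bernoulli remission, one complete
#' baseline QLQ-C30 assessment per patient plus one follow-up assessment at
#' month 24-36 for surviving patients not affected by QoL missingness, and a
#' per-patient maximum toxicity grade. All endpoints are generated
#' independently of each other (no dependence structure is imposed).
#' Deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param label Cohort label.
#' @return A [gpc_cohort()].
#' @export
simulate_cohort <- function(params = sim_params(), seed = NULL,
                            label = "synthetic") {
  validate_sim_params(params)
  gen <- function() {
    a <- simulate_arm(params$n_A, "A", params$os_rate_A, params$lr_prob[["A"]],
                      params$dm_prob[["A"]], params$cr_prob_A,
                      params$tox_grade_probs$A, params$qol_shift[["A"]], params)
    b <- simulate_arm(params$n_B, "B", params$os_rate_B, params$lr_prob[["B"]],
                      params$dm_prob[["B"]], params$cr_prob_B,
                      params$tox_grade_probs$B, params$qol_shift[["B"]], params)
    gpc_cohort(
      dplyr::bind_rows(a$patients, b$patients),
      dplyr::bind_rows(a$tox, b$tox),
      dplyr::bind_rows(a$qol, b$qol),
      label = label
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a null cohort (both arms from arm-A parameters)
#'
#' Used for type-I-error calibration: arm sizes are kept but every
#' distributional parameter of arm B is replaced by arm A's, so any apparent
#' treatment effect is noise.
#'
#' @inheritParams simulate_cohort
#' @return A [gpc_cohort()].
#' @export
simulate_null_cohort <- function(params = sim_params(), seed = NULL,
                                 label = "null") {
  null_params <- params
  null_params$os_rate_B <- params$os_rate_A
  null_params$lr_prob[["B"]] <- params$lr_prob[["A"]]
  null_params$dm_prob[["B"]] <- params$dm_prob[["A"]]
  null_params$cr_prob_B <- params$cr_prob_A
  null_params$tox_grade_probs$B <- params$tox_grade_probs$A
  null_params$qol_shift[["B"]] <- params$qol_shift[["A"]]
  simulate_cohort(null_params, seed = seed, label = label)
}
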