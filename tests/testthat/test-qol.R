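# EORTC scoring: linear transformation, eligibility, change classification

scales <- eortc_scales()
gh <- scales[scales$scale_id == "global_health", ]
pf <- scales[scales$scale_id == "physical_functioning", ]
dia <- scales[scales$scale_id == "diarrhea", ]

# build a QoL table from a list of (patient, month, item = response) entries
qol_rows <- function(...) {
  entries <- rlang::list2(...)
  purrr::map_dfr(entries, function(e) {
    tibble::tibble(patient_id = e$id, visit_month = e$month,
                   questionnaire = e$q %||% "C30",
                   item = as.integer(names(e$resp)),
                   response = as.integer(unname(e$resp)))
  })
}

test_that("linear transformation hits the scale extremes and interior values", {
  expect_equal(transform_scale(c(7, 7), range = 6, polarity = "global"), 100)
  expect_equal(transform_scale(c(1, 1), range = 6, polarity = "global"), 0)
  expect_equal(transform_scale(1, range = 3, polarity = "symptom"), 0)
  expect_equal(transform_scale(4, range = 3, polarity = "symptom"), 100)
  # best functioning (lowest raw responses) maps to 100 on functional scales
  expect_equal(transform_scale(c(1, 1), range = 3, polarity = "functional"), 100)
  expect_equal(transform_scale(c(2, 2), range = 3, polarity = "functional"),
               (1 - (2 - 1) / 3) * 100, tolerance = 1e-12)
  expect_equal(round(transform_scale(c(2, 2), range = 3, polarity = "functional"), 2),
               66.67)
})

test_that("a missing item yields a missing score, never an error", {
  expect_true(is.na(transform_scale(c(3, NA), range = 3, polarity = "symptom")))
  expect_true(is.na(transform_scale(c(3), range = 3, polarity = "symptom",
                                    n_items = 2)))
})

test_that("transformation is monotone in each item and bounded in [0, 100]", {
  withr::with_seed(8, {
    for (rep in 1:100) {
      r <- sample(1:4, 3, replace = TRUE)
      s <- transform_scale(r, range = 3, polarity = "symptom")
      expect_true(s >= 0 && s <= 100)
      j <- sample(1:3, 1)
      if (r[j] < 4) {
        r2 <- r; r2[j] <- r2[j] + 1
        expect_gte(transform_scale(r2, range = 3, polarity = "symptom"), s)
        expect_lte(transform_scale(r2, range = 3, polarity = "functional"),
                   transform_scale(r, range = 3, polarity = "functional"))
      }
    }
  })
})

test_that("eligibility picks the latest complete follow-up at >= 24 months", {
  co <- gpc_cohort(
    make_patients(3, 0),
    qol = qol_rows(
      # p001: complete visits at 12, 26, 30 -> month 30
      list(id = "p001", month = 0, resp = c(`29` = 5, `30` = 5)),
      list(id = "p001", month = 12, resp = c(`29` = 6, `30` = 6)),
      list(id = "p001", month = 26, resp = c(`29` = 4, `30` = 4)),
      list(id = "p001", month = 30, resp = c(`29` = 6, `30` = 7)),
      # p002: only a month-12 follow-up -> missing
      list(id = "p002", month = 0, resp = c(`29` = 5, `30` = 5)),
      list(id = "p002", month = 12, resp = c(`29` = 6, `30` = 6)),
      # p003: month-28 visit incomplete, month-25 complete -> month 25
      list(id = "p003", month = 0, resp = c(`29` = 4, `30` = 4)),
      list(id = "p003", month = 25, resp = c(`29` = 5, `30` = 5)),
      list(id = "p003", month = 28, resp = c(`29` = 6))
    )
  )
  el <- eligible_followup(co, gh)
  expect_identical(sort(el$patient_id), c("p001", "p003"))
  expect_equal(el$followup_month[el$patient_id == "p001"], 30)
  expect_equal(el$followup_month[el$patient_id == "p003"], 25)
  ch <- qol_changes(co, gh)
  expect_identical(ch$label[ch$patient_id == "p002"], "missing")
})

test_that("baseline must be complete too", {
  co <- gpc_cohort(
    make_patients(1, 0),
    qol = qol_rows(
      list(id = "p001", month = 0, resp = c(`29` = 5)),        # item 30 missing
      list(id = "p001", month = 30, resp = c(`29` = 6, `30` = 6))
    )
  )
  expect_identical(nrow(eligible_followup(co, gh)), 0L)
})

test_that("change classification follows polarity and flips when it reverses", {
  expect_identical(classify_change(0.5, "global"), "improved")
  expect_identical(classify_change(16.7, "symptom"), "worsened")
  expect_identical(classify_change(0, "functional"), "neutral")
  expect_identical(classify_change(NA_real_, "symptom"), "missing")
  withr::with_seed(15, {
    changes <- round(stats::rnorm(50, 0, 10), 1)
    fun <- classify_change(changes, "functional")
    sym <- classify_change(changes, "symptom")
    flip <- c(worsened = "improved", improved = "worsened", neutral = "neutral")
    expect_identical(sym, unname(flip[fun]))
    # labels agree with the sign of the change
    expect_identical(fun, dplyr::case_when(changes > 0 ~ "improved",
                                           changes < 0 ~ "worsened",
                                           TRUE ~ "neutral"))
  })
})

test_that("change table counts, percentages and t-tests are coherent", {
  co <- simulate_cohort(sim_params(n_A = 60, n_B = 60), seed = 31)
  tab <- qol_change_table(co, scales = gh)
  expect_identical(nrow(tab), 2L)  # one row per sex
  for (i in seq_len(nrow(tab))) {
    expect_identical(tab$negative_A[i] + tab$neutral_A[i] + tab$positive_A[i],
                     tab$nonmiss_A[i])
    expect_identical(tab$negative_B[i] + tab$neutral_B[i] + tab$positive_B[i],
                     tab$nonmiss_B[i])
  }
  n_a <- sum(co$patients$arm == "A" & co$patients$sex == "male")
  male <- tab[tab$sex == "male", ]
  expect_identical(male$missing_A + male$nonmiss_A, n_a)
})

test_that("identical change distributions give t = 0, p = 1", {
  qol <- dplyr::bind_rows(
    qol_rows(
      list(id = "a1", month = 0, resp = c(`29` = 4, `30` = 4)),
      list(id = "a1", month = 26, resp = c(`29` = 5, `30` = 5)),
      list(id = "a2", month = 0, resp = c(`29` = 5, `30` = 5)),
      list(id = "a2", month = 26, resp = c(`29` = 4, `30` = 4)),
      list(id = "b1", month = 0, resp = c(`29` = 4, `30` = 4)),
      list(id = "b1", month = 26, resp = c(`29` = 5, `30` = 5)),
      list(id = "b2", month = 0, resp = c(`29` = 5, `30` = 5)),
      list(id = "b2", month = 26, resp = c(`29` = 4, `30` = 4))
    )
  )
  pts <- make_patients(2, 2)
  pts$patient_id <- c("a1", "a2", "b1", "b2")
  tab <- qol_change_table(gpc_cohort(pts, qol = qol), scales = gh)
  male <- tab[tab$sex == "male", ]
  expect_equal(male$t_stat, 0)
  expect_equal(male$p_value, 1)
})

test_that("zero-variance cells report a non-computable test", {
  qol <- qol_rows(
    list(id = "a1", month = 0, resp = c(`29` = 5, `30` = 5)),
    list(id = "a1", month = 26, resp = c(`29` = 4, `30` = 4)),
    list(id = "a2", month = 0, resp = c(`29` = 5, `30` = 5)),
    list(id = "a2", month = 26, resp = c(`29` = 4, `30` = 4)),
    list(id = "b1", month = 0, resp = c(`29` = 4, `30` = 4)),
    list(id = "b1", month = 26, resp = c(`29` = 5, `30` = 5)),
    list(id = "b2", month = 0, resp = c(`29` = 4, `30` = 4)),
    list(id = "b2", month = 26, resp = c(`29` = 5, `30` = 5))
  )
  pts <- make_patients(3, 3)
  pts$patient_id <- c("a1", "a2", "f1", "b1", "b2", "f2")
  pts$sex <- c("male", "male", "female", "male", "male", "female")
  tab <- qol_change_table(gpc_cohort(pts, qol = qol), scales = gh)
  expect_true(is.na(tab$p_value[tab$sex == "male"]))
  # fewer than two non-missing patients in an arm: also not computable
  tab_f <- tab[tab$sex == "female", ]
  expect_true(is.na(tab_f$p_value))
})

test_that("t-test power on a shifted arm matches the analytic value", {
  # +5-point shift in arm B, sd 15, n = 80/arm, scaled-down replicates
  n <- 80; shift <- 5; sd <- 15; n_rep <- 200
  power <- stats::power.t.test(n = n, delta = shift, sd = sd,
                               sig.level = 0.05)$power
  withr::with_seed(99, {
    rej <- vapply(seq_len(n_rep), function(i) {
      x <- stats::rnorm(n, 0, sd); y <- stats::rnorm(n, shift, sd)
      stats::t.test(x, y)$p.value < 0.05
    }, logical(1))
  })
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(mean(rej) - power), 3.5 * se)
})
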