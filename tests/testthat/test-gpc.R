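# prioritized cascade engine: worked example, oracle equivalence, invariants

test_that("binary worked example reproduces the published pair counts", {
  r <- run_gpc(binary_cohort_tbl(156, 32, 150, 41), binary_hierarchy())
  expect_identical(r$n_pairs, 156L * 150L)
  # B wins = 41 responders x 124 non-responders, A wins = 32 x 109
  expect_identical(as.integer(r$total_b_wins), 41L * 124L)  # 5084
  expect_identical(as.integer(r$total_a_wins), 32L * 109L)  # 3488
  expect_equal(r$ntb, 41 / 150 - 32 / 156)
  expect_equal(round(r$ntb, 4), 0.0682)
  expect_equal(round(win_ratio(r), 4), round(5084 / 3488, 4))
})

test_that("engine equals the brute-force double loop on random mixed cohorts", {
  withr::with_seed(21, {
    for (rep in 1:40) {
      data <- random_patients(sample(2:10, 1), sample(2:10, 1))
      h <- random_hierarchy(4)
      cens <- sample(c("gehan", "neutral"), 1)
      expect_engine_matches_oracle(data, h, censoring = cens)
    }
  })
})

test_that("identical arms give ntb 0 and win ratio 1", {
  withr::with_seed(5, {
    half <- random_patients(12, 0)[1:12, ]
    dup <- dplyr::bind_rows(
      half,
      dplyr::mutate(half, arm = "B", patient_id = paste0(patient_id, "b"))
    )
  })
  h <- hierarchy(
    endpoint_spec("os", "survival", margin = 1, time_col = "os_time", event_col = "os_event"),
    endpoint_spec("cr", "binary", value_col = "remission")
  )
  r <- run_gpc(dup, h)
  expect_identical(r$total_a_wins, r$total_b_wins)
  expect_equal(r$ntb, 0)
  expect_equal(win_ratio(r), 1)
})

test_that("relabeling arms negates ntb and inverts the win ratio", {
  withr::with_seed(9, data <- random_patients(8, 11))
  h <- random_hierarchy(3)
  r1 <- run_gpc(data, h)
  swapped <- dplyr::mutate(data, arm = ifelse(arm == "A", "B", "A"))
  r2 <- run_gpc(swapped, h)
  expect_equal(r2$ntb, -r1$ntb)
  expect_identical(r2$total_a_wins, r1$total_b_wins)
  if (r1$total_a_wins > 0 && r1$total_b_wins > 0) {
    expect_equal(win_ratio(r2), 1 / win_ratio(r1))
  }
})

test_that("per-level counts conserve pairs and deltas sum to ntb", {
  withr::with_seed(13, data <- random_patients(9, 7))
  h <- random_hierarchy(4)
  r <- run_gpc(data, h)
  lv <- tidy(r)
  expect_identical(lv$reaching[1], r$n_pairs)
  if (nrow(lv) > 1) {
    expect_identical(lv$reaching[-1],
                     (lv$reaching - lv$a_wins - lv$b_wins)[-nrow(lv)])
  }
  expect_identical(r$total_a_wins + r$total_b_wins + r$final_ties, r$n_pairs)
  expect_equal(sum(lv$delta), r$ntb)
  expect_equal(r$ntb, r$p_better_b - r$p_better_a)
})

test_that("an all-neutral trailing level changes nothing", {
  withr::with_seed(17, data <- random_patients(10, 10))
  data$constant <- 3
  h1 <- hierarchy(endpoint_spec("cr", "binary", value_col = "remission"))
  h2 <- hierarchy(
    endpoint_spec("cr", "binary", value_col = "remission"),
    endpoint_spec("const", "ordinal", value_col = "constant")
  )
  r1 <- run_gpc(data, h1)
  r2 <- run_gpc(data, h2)
  expect_identical(r1$total_a_wins, r2$total_a_wins)
  expect_identical(r1$total_b_wins, r2$total_b_wins)
  expect_equal(r1$ntb, r2$ntb)
})

test_that("ntb is monotone in the arm-B responder count for a binary endpoint", {
  ntbs <- vapply(0:12, function(k) {
    run_gpc(binary_cohort_tbl(10, 4, 12, k), binary_hierarchy())$ntb
  }, numeric(1))
  expect_true(all(diff(ntbs) >= 0))
})

test_that("per_endpoint_delta equals a one-level run and the binary algebra", {
  withr::with_seed(3, data <- random_patients(14, 9))
  spec <- endpoint_spec("os", "survival", margin = 1,
                        time_col = "os_time", event_col = "os_event")
  expect_equal(glance(per_endpoint_delta(data, spec)),
               glance(run_gpc(data, hierarchy(spec))))
  # no missing values: delta is exactly p_B - p_A
  for (k in list(c(5, 2, 7, 3), c(6, 0, 5, 5), c(8, 8, 9, 1))) {
    r <- run_gpc(binary_cohort_tbl(k[1], k[2], k[3], k[4]), binary_hierarchy())
    expect_equal(r$ntb, k[4] / k[3] - k[2] / k[1])
  }
})

test_that("survival delta matches the Mann-Whitney identity without censoring", {
  withr::with_seed(31, {
    n <- 500
    ta <- stats::rexp(n, 1 / 20)
    tb <- stats::rexp(n, 1 / 30)  # arm B stochastically larger
    data <- make_patients(n, n, os_time = c(ta, tb), os_event = rep(TRUE, 2 * n))
  })
  spec <- endpoint_spec("os", "survival", margin = 0,
                        time_col = "os_time", event_col = "os_event")
  r <- per_endpoint_delta(data, spec)
  # theta = P(T_B > T_A) = 30 / (20 + 30); delta = 2 theta - 1; MC SE of the
  # U-statistic estimate is below sqrt(theta (1 - theta)) * sqrt(2 / n)
  theta <- 30 / 50
  se <- sqrt(theta * (1 - theta)) * sqrt(2 / n)
  expect_lt(abs(r$ntb - (2 * theta - 1)), 3 * se)
})

test_that("conditional decomposition reports both denominators", {
  r1 <- run_gpc(binary_cohort_tbl(10, 4, 10, 7), binary_hierarchy())
  d1 <- decompose_conditional(r1)
  expect_equal(d1$a_of_all, d1$a_of_reaching)
  expect_equal(d1$b_of_all, d1$b_of_reaching)

  # all pairs tied at level 1: level-2 conditional equals its standalone delta
  data <- binary_cohort_tbl(6, 2, 8, 5)
  data$constant <- 1
  h <- hierarchy(
    endpoint_spec("const", "ordinal", value_col = "constant"),
    endpoint_spec("cr", "binary", value_col = "remission")
  )
  d2 <- decompose_conditional(run_gpc(data, h))
  expect_identical(d2$reaching[2], 48L)
  lone <- run_gpc(data, binary_hierarchy())
  expect_equal(d2$b_of_reaching[2] - d2$a_of_reaching[2], lone$ntb)

  # a level no pair reaches is flagged
  all_win <- make_patients(3, 3, remission = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  h3 <- hierarchy(
    endpoint_spec("cr", "binary", value_col = "remission"),
    endpoint_spec("cr2", "binary", value_col = "remission")
  )
  d3 <- decompose_conditional(run_gpc(all_win, h3))
  expect_true(d3$no_pairs_reached[2])
  expect_equal(d3$a_of_reaching[2], 0)
})

test_that("configuration errors are caught", {
  expect_error(run_gpc(make_patients(3, 0), binary_hierarchy()), "non-empty")
  co <- small_full_cohort(seed = 2, n = 6)
  h <- hierarchy(endpoint_spec("ghost", "ordinal", value_col = "not_a_column"))
  expect_error(run_gpc(co, h), "ghost")
  expect_error(hierarchy(), "at least one endpoint")
  expect_error(endpoint_spec("x", "survival", margin = 1), "time_col")
})

test_that("tidy, glance and autoplot methods behave", {
  r <- run_gpc(binary_cohort_tbl(10, 3, 10, 6), binary_hierarchy())
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_identical(nrow(g), 1L)
  expect_named(g, c("n_pairs", "total_a_wins", "total_b_wins", "final_ties",
                    "p_better_a", "p_better_b", "ntb", "win_ratio"))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
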