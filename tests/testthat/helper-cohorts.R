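# shared builders and the independent brute-force GPC oracle

# patient table with all hierarchy columns, defaulting to an uneventful record
make_patients <- function(n_a, n_b, ...) {
  n <- n_a + n_b
  base <- tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    arm = rep(c("A", "B"), c(n_a, n_b)),
    sex = rep("male", n),
    os_time = rep(60, n), os_event = rep(FALSE, n),
    lr_time = rep(60, n), lr_event = rep(FALSE, n),
    dm_time = rep(60, n), dm_event = rep(FALSE, n),
    remission = rep(FALSE, n)
  )
  mods <- rlang::list2(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# cohort with remission split (k_a of n_a, k_b of n_b responders)
binary_cohort_tbl <- function(n_a, k_a, n_b, k_b) {
  make_patients(n_a, n_b,
    remission = c(rep(TRUE, k_a), rep(FALSE, n_a - k_a),
                  rep(TRUE, k_b), rep(FALSE, n_b - k_b)))
}

binary_hierarchy <- function() {
  hierarchy(endpoint_spec("remission", "binary", value_col = "remission"))
}

# brute-force prioritized GPC: explicit double loop over ordered pairs,
# cascading with the scalar comparison rules; independent of the engine's
# matrix path
brute_gpc <- function(data, h, censoring = "gehan") {
  a_rows <- data[data$arm == "A", ]
  b_rows <- data[data$arm == "B", ]
  n_levels <- nrow(h)
  a_wins <- b_wins <- neutral <- uninf <- integer(n_levels)
  tot_a <- tot_b <- 0L
  for (i in seq_len(nrow(a_rows))) {
    for (j in seq_len(nrow(b_rows))) {
      for (l in seq_len(n_levels)) {
        s <- h[l, ]
        verdict <- switch(s$kind,
          survival = compare_survival(
            list(time = a_rows[[s$time_col]][i], event = a_rows[[s$event_col]][i]),
            list(time = b_rows[[s$time_col]][j], event = b_rows[[s$event_col]][j]),
            tau = s$margin, censoring = censoring),
          incidence = compare_incidence(
            list(time = a_rows[[s$time_col]][i], event = a_rows[[s$event_col]][i]),
            list(time = b_rows[[s$time_col]][j], event = b_rows[[s$event_col]][j]),
            tau = s$margin, censoring = censoring),
          binary = compare_binary(a_rows[[s$value_col]][i], b_rows[[s$value_col]][j]),
          ordinal = compare_ordinal(a_rows[[s$value_col]][i], b_rows[[s$value_col]][j],
                                    direction = s$direction)
        )
        if (verdict == "A_wins") {
          a_wins[l] <- a_wins[l] + 1L; tot_a <- tot_a + 1L; break
        } else if (verdict == "B_wins") {
          b_wins[l] <- b_wins[l] + 1L; tot_b <- tot_b + 1L; break
        } else if (verdict == "neutral") {
          neutral[l] <- neutral[l] + 1L
        } else {
          uninf[l] <- uninf[l] + 1L
        }
      }
    }
  }
  n_pairs <- nrow(a_rows) * nrow(b_rows)
  list(a_wins = a_wins, b_wins = b_wins, neutral = neutral, uninf = uninf,
       total_a = tot_a, total_b = tot_b,
       ntb = (tot_b - tot_a) / n_pairs)
}

# random patient table with censoring, missingness and ties, for oracle tests
random_patients <- function(n_a, n_b) {
  n <- n_a + n_b
  rnd_tte <- function() {
    t <- round(stats::rexp(n, 1 / 24), 1)
    list(time = t, event = stats::runif(n) < 0.6)
  }
  os <- rnd_tte(); lr <- rnd_tte(); dm <- rnd_tte()
  make_patients(n_a, n_b,
    os_time = os$time, os_event = os$event,
    lr_time = lr$time, lr_event = lr$event,
    dm_time = dm$time, dm_event = dm$event,
    remission = sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                       prob = c(0.35, 0.55, 0.10)),
    grade = sample(c(0:4, NA), n, replace = TRUE)
  )
}

# random hierarchy of up to `max_levels` distinct endpoint kinds
random_hierarchy <- function(max_levels = 4) {
  pool <- list(
    endpoint_spec("os", "survival", margin = sample(c(0, 1, 2), 1),
                  time_col = "os_time", event_col = "os_event"),
    endpoint_spec("lr", "incidence", margin = sample(c(0, 1), 1),
                  time_col = "lr_time", event_col = "lr_event"),
    endpoint_spec("dm", "incidence", margin = 1,
                  time_col = "dm_time", event_col = "dm_event"),
    endpoint_spec("cr", "binary", value_col = "remission"),
    endpoint_spec("tox", "ordinal", direction = "lower_better",
                  value_col = "grade")
  )
  k <- sample(seq_len(max_levels), 1)
  picks <- sample(seq_along(pool), k)
  rlang::exec(hierarchy, !!!pool[picks])
}

expect_engine_matches_oracle <- function(data, h, censoring = "gehan") {
  r <- run_gpc(data, h, censoring = censoring)
  o <- brute_gpc(data, h, censoring = censoring)
  expect_identical(as.integer(r$levels$a_wins), o$a_wins)
  expect_identical(as.integer(r$levels$b_wins), o$b_wins)
  expect_identical(as.integer(r$levels$neutral), o$neutral)
  expect_identical(as.integer(r$levels$uninformative), o$uninf)
  expect_equal(r$ntb, o$ntb)
}

# small cohort with QoL and toxicity visits for end-to-end tests
small_full_cohort <- function(seed = 7, n = 24) {
  p <- sim_params(n_A = n, n_B = n)
  simulate_cohort(p, seed = seed, label = "unit")
}
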