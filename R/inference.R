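#' Resampling specification for GPC inference
#'
#' @param n_boot Number of bootstrap resamples (>= 1; >= 100 recommended).
#' @param n_perm Number of arm-label permutations (>= 1; >= 100 recommended).
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @param seed Integer seed; every resampling run is deterministic given it.
#' @return A list of class `resample_spec`.
#' @export
resample_spec <- function(n_boot = 2000, n_perm = 2000, alpha = 0.05,
                          seed = NULL) {
  if (n_boot < 1 || n_perm < 1) rlang::abort("n_boot and n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must be in (0, 1)")
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 alpha = alpha, seed = seed), class = "resample_spec")
}

# shared setup: prepared data + full patient-by-patient score matrices,
# so resamples only index into precomputed verdicts
gpc_resample_setup <- function(cohort, h, censoring, scales, min_month) {
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
  list(data = data, idx_a = idx_a, idx_b = idx_b,
       mats = score_matrices(data, h, censoring = censoring))
}

resample_stat <- function(mats, idx_a, idx_b) {
  n_pairs <- length(idx_a) * length(idx_b)
  undecided <- rep(TRUE, n_pairs)
  tot_a <- 0L; tot_b <- 0L
  for (m in mats) {
    v <- m[idx_a, idx_b, drop = FALSE]
    a <- v == .VERDICT_A & undecided
    b <- v == .VERDICT_B & undecided
    tot_a <- tot_a + sum(a)
    tot_b <- tot_b + sum(b)
    undecided <- undecided & !(a | b)
  }
  c(ntb = (tot_b - tot_a) / n_pairs,
    win_ratio = if (tot_a > 0) tot_b / tot_a else Inf)
}

#' Stratified bootstrap confidence intervals for NTB and win ratio
#'
#' Resamples patients with replacement *within* each arm, recomputes the full
#' prioritized GPC on every resample, and returns percentile intervals for
#' the net treatment benefit and the win ratio. Degenerate resamples (an arm
#' collapsing onto few distinct patients) are included, not rejected.
#'
#' @inheritParams run_gpc
#' @param spec A [resample_spec()].
#' @return A list of class `gpc_bootstrap`: `ntb` and `win_ratio` point
#'   estimates with `lower`/`upper` bounds, the spec, and the bootstrap
#'   replicate tibble in `$replicates`.
#' @export
gpc_bootstrap <- function(cohort, h = cao_aro_aio12_hierarchy(),
                          spec = resample_spec(),
                          censoring = c("gehan", "neutral"),
                          scales = eortc_scales(), min_month = 24) {
  censoring <- match.arg(censoring)
  setup <- gpc_resample_setup(cohort, h, censoring, scales, min_month)
  obs <- resample_stat(setup$mats, setup$idx_a, setup$idx_b)
  run <- function() {
    reps <- purrr::map(seq_len(spec$n_boot), function(i) {
      ia <- sample(setup$idx_a, replace = TRUE)
      ib <- sample(setup$idx_b, replace = TRUE)
      resample_stat(setup$mats, ia, ib)
    })
    do.call(rbind, reps)
  }
  reps <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  probs <- c(spec$alpha / 2, 1 - spec$alpha / 2)
  wr <- reps[, "win_ratio"]
  structure(list(
    ntb = list(estimate = unname(obs["ntb"]),
               lower = unname(stats::quantile(reps[, "ntb"], probs[1])),
               upper = unname(stats::quantile(reps[, "ntb"], probs[2]))),
    win_ratio = list(estimate = unname(obs["win_ratio"]),
                     lower = unname(stats::quantile(wr, probs[1], names = FALSE)),
                     upper = unname(stats::quantile(wr, probs[2], names = FALSE))),
    spec = spec,
    replicates = tibble::tibble(ntb = reps[, "ntb"], win_ratio = wr)
  ), class = "gpc_bootstrap")
}

#' @export
print.gpc_bootstrap <- function(x, ...) {
  lvl <- 100 * (1 - x$spec$alpha)
  cat(sprintf("<gpc_bootstrap> %d stratified resamples\n", x$spec$n_boot))
  cat(sprintf("  NTB %.4f  %.0f%% CI [%.4f, %.4f]\n",
              x$ntb$estimate, lvl, x$ntb$lower, x$ntb$upper))
  cat(sprintf("  win ratio %.2f  %.0f%% CI [%.2f, %.2f]\n",
              x$win_ratio$estimate, lvl, x$win_ratio$lower, x$win_ratio$upper))
  invisible(x)
}

#' Permutation p-value for the net treatment benefit
#'
#' Permutes arm labels (preserving arm sizes), recomputes the prioritized GPC
#' for each permutation, and returns the add-one two-sided p-value
#' `p = (1 + #\{|NTB*| >= |NTB|\}) / (1 + n_perm)`, which can never be zero.
#'
#' @inheritParams gpc_bootstrap
#' @return A list of class `gpc_permutation`: `p_value`, observed `ntb`, the
#'   spec, and the permuted statistics in `$perm_ntb`.
#' @export
gpc_permutation <- function(cohort, h = cao_aro_aio12_hierarchy(),
                            spec = resample_spec(),
                            censoring = c("gehan", "neutral"),
                            scales = eortc_scales(), min_month = 24) {
  censoring <- match.arg(censoring)
  setup <- gpc_resample_setup(cohort, h, censoring, scales, min_month)
  obs <- resample_stat(setup$mats, setup$idx_a, setup$idx_b)[["ntb"]]
  all_idx <- c(setup$idx_a, setup$idx_b)
  n_a <- length(setup$idx_a)
  run <- function() {
    vapply(seq_len(spec$n_perm), function(i) {
      shuffled <- sample(all_idx)
      resample_stat(setup$mats, shuffled[seq_len(n_a)],
                    shuffled[-seq_len(n_a)])[["ntb"]]
    }, numeric(1))
  }
  perm <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + spec$n_perm)
  structure(list(p_value = p, ntb = obs, spec = spec, perm_ntb = perm),
            class = "gpc_permutation")
}

#' @export
print.gpc_permutation <- function(x, ...) {
  cat(sprintf("<gpc_permutation> %d permutations\n", x$spec$n_perm))
  cat(sprintf("  observed NTB %.4f  two-sided p = %.4f\n", x$ntb, x$p_value))
  invisible(x)
}
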