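#' Task-sensitivity test over directed pairs
#'
#' Screens each directed pair for stable task-evoked connectivity
#' (coefficient of variation of the task values across units below
#' `cv_threshold`), then tests for a task-related increase over rest with a
#' within-unit right-tailed paired t-test, Benjamini-Hochberg corrected
#' across the tested pairs. A pair is declared task-evoked when its FDR
#' q-value falls below `q_threshold`.
#'
#' @param samples data.frame with columns `unit_id`, `pair`, `task_value`,
#'   `rest_value`; one row per unit (subject) and directed pair. Unit-level
#'   values are typically means over that unit's trials.
#' @param cv_threshold coefficient-of-variation screen (default 0.30).
#' @param q_threshold FDR threshold (default 0.02).
#' @return object of class `test_report`: list with `table` (per-pair
#'   statistics: cv, t, p, q, significant), `significant_set`, `excluded`
#'   (pairs failing the CV screen or with undefined CV) and the thresholds.
#' @export
sensitivity_test <- function(samples, cv_threshold = 0.30,
                             q_threshold = 0.02) {
  stopifnot(all(c("unit_id", "pair", "task_value", "rest_value")
                %in% names(samples)),
            cv_threshold > 0, cv_threshold < 1,
            q_threshold > 0, q_threshold < 1)
  pairs <- unique(samples$pair)
  rows <- lapply(pairs, function(p) {
    sub <- samples[samples$pair == p, ]
    if (nrow(sub) < 3) stop("pair ", p, " has fewer than 3 units")
    mu <- mean(sub$task_value)
    cv <- if (mu <= 0) NA_real_ else stats::sd(sub$task_value) / mu
    data.frame(pair = p, n_units = nrow(sub), cv = cv,
               mean_task = mu, mean_rest = mean(sub$rest_value),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$t_stat <- NA_real_
  tab$p_value <- NA_real_
  keep <- !is.na(tab$cv) & tab$cv < cv_threshold
  for (i in which(keep)) {
    sub <- samples[samples$pair == tab$pair[i], ]
    tt <- stats::t.test(sub$task_value, sub$rest_value, paired = TRUE,
                        alternative = "greater")
    tab$t_stat[i] <- unname(tt$statistic)
    tab$p_value[i] <- tt$p.value
  }
  tab$q_value <- NA_real_
  tab$q_value[keep] <- stats::p.adjust(tab$p_value[keep], method = "BH")
  tab$significant <- !is.na(tab$q_value) & tab$q_value < q_threshold
  structure(
    list(table = tab,
         significant_set = tab$pair[tab$significant],
         excluded = tab$pair[!keep],
         cv_threshold = cv_threshold, q_threshold = q_threshold),
    class = "test_report"
  )
}

#' Directional-asymmetry specificity test
#'
#' Resting-state null check on a bilateral pair: per scan, the directional
#' asymmetry is the absolute difference between the time-averaged
#' connectivity of the two directions; the reference scan-to-scan
#' variability is the standard deviation, across scans, of the per-scan
#' time-averaged connectivity (average of the two directions). The null
#' hypothesis "median asymmetry >= variability" is tested with a left-tailed
#' Wilcoxon signed-rank test of (asymmetry - variability); rejection
#' (p < `alpha`) supports directional specificity — asymmetry is small
#' relative to ordinary scan-to-scan fluctuation.
#'
#' @param samples data.frame with columns `scan_id`, `forward_mean`,
#'   `backward_mean`: time-averaged connectivity of the two directions of
#'   the same unordered pair, one row per scan. At least 6 scans.
#' @param alpha rejection threshold (default 0.02).
#' @return `test_report` list with `statistic` (V), `p_value`, `reject`,
#'   `asymmetry` (per scan), `variability` and `alpha`.
#' @export
specificity_test <- function(samples, alpha = 0.02) {
  stopifnot(all(c("scan_id", "forward_mean", "backward_mean")
                %in% names(samples)))
  n <- nrow(samples)
  if (n < 6) stop("specificity test needs at least 6 scans, got ", n)
  asym <- abs(samples$forward_mean - samples$backward_mean)
  per_scan_mean <- (samples$forward_mean + samples$backward_mean) / 2
  variability <- stats::sd(per_scan_mean)
  d <- asym - variability
  # exact null distribution only when it is well defined (no zeros/ties);
  # otherwise the normal approximation with continuity correction
  exact_ok <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  wt <- stats::wilcox.test(asym, mu = variability, alternative = "less",
                           exact = exact_ok, correct = TRUE)
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         reject = wt$p.value < alpha, asymmetry = asym,
         variability = variability, alpha = alpha, n_scans = n),
    class = "test_report"
  )
}

#' Bootstrap correlation of paired window series across scans
#'
#' Cross-modal time-resolved correspondence: each bootstrap replicate
#' resamples window indices with replacement independently within every
#' scan, concatenates the paired (series_a, series_b) values across scans,
#' and computes their Pearson correlation. Scans with fewer than 2 windows
#' are excluded with a warning; window pairs with a missing value in either
#' series are dropped before resampling.
#'
#' @param series_a,series_b named lists of numeric vectors, one per scan;
#'   matching names and per-scan lengths (shared window index).
#' @param n_boot number of replicates, >= 100.
#' @param seed integer seed; the operation is bit-reproducible given a seed.
#' @param conf confidence level of the percentile interval.
#' @return list of class `bootstrap_summary`: `replicates`, `mean`,
#'   `ci` (percentile), `p_value` (one-sided, fraction of replicates <= 0),
#'   `plug_in` (correlation without resampling), `n_windows`.
#' @export
bootstrap_window_correlation <- function(series_a, series_b, n_boot = 1000,
                                         seed = 1, conf = 0.95) {
  stopifnot(length(series_a) == length(series_b), n_boot >= 100)
  keep <- vapply(seq_along(series_a), function(i) {
    ok <- is.finite(series_a[[i]]) & is.finite(series_b[[i]])
    series_a[[i]] <<- series_a[[i]][ok]
    series_b[[i]] <<- series_b[[i]][ok]
    length(series_a[[i]]) >= 2
  }, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " scan(s) with < 2 usable windows excluded")
    series_a <- series_a[keep]
    series_b <- series_b[keep]
  }
  if (length(series_a) == 0) stop("no usable scans")
  plug_in <- stats::cor(unlist(series_a), unlist(series_b))
  reps <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    xs <- ys <- vector("list", length(series_a))
    for (i in seq_along(series_a)) {
      idx <- sample.int(length(series_a[[i]]), replace = TRUE)
      xs[[i]] <- series_a[[i]][idx]
      ys[[i]] <- series_b[[i]][idx]
    }
    reps[b] <- stats::cor(unlist(xs), unlist(ys))
  }
  .bootstrap_summary(reps, plug_in, conf,
                     n_windows = sum(lengths(series_a)))
}

#' Bootstrap correlation of time-averaged matrices across scans
#'
#' Cross-modal spatial correspondence: each replicate resamples scans with
#' replacement, averages the per-scan matrices of each modality over the
#' resampled scans, vectorizes the off-diagonal directed entries, and
#' computes the Pearson correlation between the two modality averages.
#'
#' @param matrices_a,matrices_b lists of square matrices (same region set),
#'   one per scan, matched across modalities.
#' @inheritParams bootstrap_window_correlation
#' @return a `bootstrap_summary` (see [bootstrap_window_correlation()]).
#' @export
bootstrap_matrix_correlation <- function(matrices_a, matrices_b,
                                         n_boot = 1000, seed = 1,
                                         conf = 0.95) {
  stopifnot(length(matrices_a) == length(matrices_b), n_boot >= 100)
  n_scan <- length(matrices_a)
  if (n_scan < 2) stop("bootstrap over scans needs at least 2 scans")
  offdiag <- function(m) m[row(m) != col(m)]
  avg_vec <- function(mats, idx) {
    offdiag(Reduce(`+`, mats[idx]) / length(idx))
  }
  plug_in <- stats::cor(avg_vec(matrices_a, seq_len(n_scan)),
                        avg_vec(matrices_b, seq_len(n_scan)))
  reps <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_scan, replace = TRUE)
    reps[b] <- stats::cor(avg_vec(matrices_a, idx), avg_vec(matrices_b, idx))
  }
  .bootstrap_summary(reps, plug_in, conf, n_windows = n_scan)
}

.bootstrap_summary <- function(reps, plug_in, conf, n_windows) {
  alpha <- 1 - conf
  structure(
    list(replicates = reps, mean = mean(reps),
         ci = unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2))),
         p_value = mean(reps <= 0), plug_in = plug_in,
         n_windows = n_windows, conf = conf),
    class = "bootstrap_summary"
  )
}

# Save/restore the global RNG state so seeded operations do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
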