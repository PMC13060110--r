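#' Plan sliding windows over a time series
#'
#' Returns the maximal set of fully contained windows of `length_samples`
#' spaced `step_samples` apart: `M = floor((T - n) / step) + 1` windows.
#' Starts are 1-based sample indices.
#'
#' @param n_timepoints total series length `T`.
#' @param length_samples window length `n` in samples.
#' @param step_samples step between consecutive window starts, >= 1.
#' @return object of class `window_plan`: list with `length_samples`,
#'   `step_samples`, `starts` (1-based) and `n_windows`.
#' @examples
#' plan_windows(600, 50, 1)$n_windows  # 551
#' @export
plan_windows <- function(n_timepoints, length_samples, step_samples = 1) {
  stopifnot(step_samples >= 1, length_samples >= 2)
  if (length_samples > n_timepoints) {
    stop("window length (", length_samples, ") exceeds series length (",
         n_timepoints, ")", call. = FALSE)
  }
  m <- (n_timepoints - length_samples) %/% step_samples + 1L
  structure(
    list(length_samples = as.integer(length_samples),
         step_samples = as.integer(step_samples),
         starts = 1L + step_samples * (seq_len(m) - 1L),
         n_windows = as.integer(m)),
    class = "window_plan"
  )
}

#' Convert a window length in seconds to samples
#'
#' Rounds down with a warning when the duration is not an integer multiple
#' of the sampling interval.
#'
#' @param seconds window duration in seconds.
#' @param tr_seconds sampling interval in seconds.
#' @return integer number of samples.
#' @export
window_samples_from_seconds <- function(seconds, tr_seconds) {
  ratio <- seconds / tr_seconds
  n <- as.integer(floor(ratio + 1e-9))
  if (abs(ratio - n) > 1e-9) {
    warning("window of ", seconds, " s is not a whole number of TRs (",
            tr_seconds, " s); truncated to ", n, " samples")
  }
  n
}

#' Sliding-window correlation (SWC)
#'
#' Pearson correlation of the raw sender and receiver segments in each
#' window; the non-directional baseline measure. Windows with a constant
#' segment yield `NA`.
#'
#' @param x,y numeric vectors of equal length `T`.
#' @param plan a [window_plan()].
#' @return numeric vector of length `plan$n_windows`.
#' @export
sliding_swc <- function(x, y, plan) {
  stopifnot(length(x) == length(y))
  vapply(plan$starts, function(s) {
    xi <- x[s:(s + plan$length_samples - 1L)]
    yi <- y[s:(s + plan$length_samples - 1L)]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) NA_real_ else stats::cor(xi, yi)
  }, numeric(1))
}

#' Sliding-window directed channel measures for one ordered pair
#'
#' For each window: selects the channel order by information criterion, fits
#' the nonnegative FIR channel, and computes its water-filling capacity.
#' Returns the four aligned window series of the framework: channel capacity,
#' prediction-correlation (SWpC), plain correlation (SWC), and connection
#' duration (the selected order, in TR units). Lagged sender values for a
#' window are taken from the preceding samples of the full series when
#' available ("lookback"), otherwise the affected leading rows are truncated.
#'
#' @param sender,receiver numeric vectors of equal length `T`.
#' @param plan a [window_plan()].
#' @param config an [order_config()].
#' @param grid_size DFT length for the capacity estimator.
#' @param log_base `"bits"` or `"nats"`.
#' @param tr_seconds sampling interval (labels `window_start_s`).
#' @param use_lookback take pre-window sender history from the series
#'   (default); `FALSE` forces row truncation in the first windows.
#' @return data.frame with columns `window_index`, `window_start_s`,
#'   `capacity`, `pcorr`, `swc`, `duration_trs`. Degenerate windows carry
#'   `NA` in all four measures so that the window index set stays aligned
#'   across measures and across modalities.
#' @export
sliding_capacity <- function(sender, receiver, plan,
                             config = order_config("BIC"),
                             grid_size = 4096,
                             log_base = c("bits", "nats"),
                             tr_seconds = 1,
                             use_lookback = TRUE) {
  log_base <- match.arg(log_base)
  stopifnot(length(sender) == length(receiver))
  n <- plan$length_samples
  k_max <- config$k_max
  if (is.null(k_max)) k_max <- max(1L, min(8L, n %/% 10L))
  m <- plan$n_windows
  capacity <- pcorr <- swc <- rep(NA_real_, m)
  duration <- rep(NA_integer_, m)
  for (w in seq_len(m)) {
    s <- plan$starts[w]
    idx <- s:(s + n - 1L)
    lb <- if (use_lookback && s > 1L) {
      sender[max(1L, s - k_max + 1L):(s - 1L)]
    } else {
      numeric(0)
    }
    fit <- tryCatch(
      select_order(window_segment(sender[idx], receiver[idx], lb, tr_seconds),
                   config),
      error = function(e) NULL
    )
    if (is.null(fit)) next   # degenerate window stays NA at index w
    capacity[w] <- channel_capacity(fit, grid_size, log_base)$capacity
    pcorr[w] <- fit$pcorr
    duration[w] <- fit$order
    swc[w] <- if (stats::sd(sender[idx]) > 0 && stats::sd(receiver[idx]) > 0) {
      stats::cor(sender[idx], receiver[idx])
    } else {
      NA_real_
    }
  }
  data.frame(window_index = seq_len(m),
             window_start_s = (plan$starts - 1L) * tr_seconds,
             capacity = capacity, pcorr = pcorr, swc = swc,
             duration_trs = duration)
}

#' Sliding-window measures for every directed pair of a region set
#'
#' Runs [sliding_capacity()] over all ordered pairs of a multi-region time
#' series set and stacks the results in long format.
#'
#' @param ts a `roi_ts` object (see [roi_timeseries()]).
#' @param plan a [window_plan()]; defaults to windows of `window_seconds`
#'   with step 1 sample.
#' @param window_seconds window duration used when `plan` is `NULL`.
#' @inheritParams sliding_capacity
#' @return data.frame with columns `scan_id`, `sender`, `receiver`,
#'   `window_index`, `window_start_s`, `capacity`, `pcorr`, `swc`,
#'   `duration_trs`.
#' @export
connectivity_pairs <- function(ts, plan = NULL, window_seconds = 50,
                               config = order_config("BIC"),
                               grid_size = 4096,
                               log_base = c("bits", "nats"),
                               use_lookback = TRUE) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(ts, "roi_ts"))
  if (is.null(plan)) {
    n <- window_samples_from_seconds(window_seconds, ts$tr_seconds)
    plan <- plan_windows(ncol(ts$values), n, 1L)
  }
  labels <- ts$roi_labels
  out <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (i == j) next
      res <- sliding_capacity(ts$values[i, ], ts$values[j, ], plan,
                              config = config, grid_size = grid_size,
                              log_base = log_base,
                              tr_seconds = ts$tr_seconds,
                              use_lookback = use_lookback)
      res$scan_id <- ts$scan_id
      res$sender <- labels[i]
      res$receiver <- labels[j]
      out[[length(out) + 1L]] <- res
    }
  }
  long <- do.call(rbind, out)
  long[, c("scan_id", "sender", "receiver", "window_index", "window_start_s",
           "capacity", "pcorr", "swc", "duration_trs")]
}

#' Time-averaged directed connectivity matrix of one scan
#'
#' Averages the chosen window measure across all windows for each directed
#' pair. Missing windows are excluded from the mean; the diagonal is `NA`.
#'
#' @param long data.frame as returned by [connectivity_pairs()].
#' @param measure one of `"capacity"`, `"pcorr"`, `"swc"`, `"duration_trs"`.
#' @return square matrix with region labels on both dimensions.
#' @export
time_average_matrix <- function(long, measure = "capacity") {
  stopifnot(measure %in% c("capacity", "pcorr", "swc", "duration_trs"))
  labels <- sort(unique(c(long$sender, long$receiver)))
  mat <- matrix(NA_real_, length(labels), length(labels),
                dimnames = list(sender = labels, receiver = labels))
  agg <- stats::aggregate(long[[measure]],
                          by = list(sender = long$sender,
                                    receiver = long$receiver),
                          FUN = function(v) mean(v, na.rm = TRUE))
  for (r in seq_len(nrow(agg))) {
    mat[agg$sender[r], agg$receiver[r]] <- agg$x[r]
  }
  mat
}
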