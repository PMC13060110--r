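#' Standardize a signal to zero mean and unit root-mean-square
#'
#' Removes the mean and divides by the root mean square (RMS, computed with
#' divisor `n`, the population convention). After standardization the signal
#' has zero mean and unit power, which makes the unit sender-power constraint
#' of the capacity estimator exact and gives the order-1 channel fit its
#' closed form.
#'
#' @param values numeric vector, length >= 2, not all identical.
#' @return numeric vector of the same length with mean 0 and RMS 1.
#' @examples
#' standardize(c(2, 0))        # c(1, -1)
#' round(mean(standardize(rnorm(100))), 12)
#' @export
standardize <- function(values) {
  if (length(values) < 2) {
    stop("standardize() needs at least 2 samples")
  }
  if (anyNA(values)) stop("standardize() does not accept missing values")
  centred <- values - mean(values)
  rms <- sqrt(mean(centred^2))
  if (rms == 0) {
    stop("degenerate signal: input is constant, standardization undefined",
         call. = FALSE)
  }
  centred / rms
}

#' Construct a window segment for channel fitting
#'
#' Bundles the sender and receiver samples of one analysis window together
#' with up to `k_max - 1` sender samples immediately preceding the window
#' (the "lookback"), which supply the lagged values needed by the
#' convolution matrix near the window start.
#'
#' @param sender numeric vector of sender-region samples in the window.
#' @param receiver numeric vector of receiver-region samples, same length.
#' @param lookback numeric vector of sender samples immediately preceding the
#'   window (oldest first); may be empty.
#' @param tr_seconds sampling interval in seconds.
#' @return an object of class `window_segment`.
#' @export
window_segment <- function(sender, receiver, lookback = numeric(0),
                           tr_seconds = 1) {
  if (length(sender) != length(receiver)) {
    stop("sender and receiver must have identical length")
  }
  if (length(sender) < 2) stop("window length must be at least 2")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(
    list(sender = as.numeric(sender), receiver = as.numeric(receiver),
         lookback = as.numeric(lookback), n = length(sender),
         tr_seconds = tr_seconds),
    class = "window_segment"
  )
}

#' Build the lagged (convolution) design matrix of a window
#'
#' Row `t`, column `j` holds the sender value at time `t - j + 1` (lags
#' `0 ... order-1`); each column is then standardized independently. Lagged
#' values before the window start are taken from the segment's lookback
#' buffer. When the lookback is too short and `truncate = TRUE`, the leading
#' rows that would need unobserved history are dropped (together with the
#' matching receiver samples); with `truncate = FALSE` a too-early window is
#' an error.
#'
#' @param segment a [window_segment()].
#' @param order number of FIR taps (columns), >= 1.
#' @param truncate drop rows with incomplete lag history instead of erroring.
#' @param standardize_columns standardize each column (the default; raw
#'   lagged values are only useful for inspection).
#' @return list with `X` (matrix, rows x order), `y` (receiver samples for the
#'   retained rows, unstandardized) and `rows_dropped`.
#' @export
build_convolution_matrix <- function(segment, order, truncate = TRUE,
                                     standardize_columns = TRUE) {
  stopifnot(inherits(segment, "window_segment"), order >= 1)
  n <- segment$n
  lb <- segment$lookback
  need <- order - 1L
  have <- length(lb)
  missing_hist <- max(0L, need - have)
  if (missing_hist > 0L && !truncate) {
    stop("window too early: ", missing_hist,
         " lookback sample(s) missing for order ", order, call. = FALSE)
  }
  # full sender history for this window, oldest first
  hist <- c(lb, segment$sender)
  rows <- seq.int(missing_hist + 1L, n)
  if (length(rows) < 2L) {
    stop("fewer than 2 rows remain after lag truncation", call. = FALSE)
  }
  X <- matrix(0, nrow = length(rows), ncol = order)
  for (j in seq_len(order)) {
    # position of x_{t-(j-1)} inside hist for window-time t
    X[, j] <- hist[have + rows - (j - 1L)]
  }
  if (standardize_columns) {
    X <- apply(X, 2, standardize)
    if (!is.matrix(X)) X <- matrix(X, ncol = order)
  }
  list(X = X, y = segment$receiver[rows], rows_dropped = missing_hist)
}
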