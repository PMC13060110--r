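#' Equivalent-input-noise spectrum of a fitted channel
#'
#' Evaluates the channel frequency response on an `N`-point DFT grid by FFT
#' of the zero-padded tap vector and refers the additive noise to the input:
#' `S_EIN(f_l) = sigma^2 / |H(f_l)|^2`. Bins where the response vanishes
#' carry `Inf`; they can never be selected by water-filling. For real taps
#' the spectrum is conjugate-symmetric (`values[l] == values[N - l + 2]` in
#' 1-based indexing).
#'
#' @param fit a `channel_fit` (or any list with `coefficients` and
#'   `noise_variance`).
#' @param grid_size DFT length `N`, >= max(2, order).
#' @param tr_seconds sampling interval used only to label the frequency axis.
#' @return object of class `ein_spectrum`: list with `values` (length `N`,
#'   nonnegative, possibly `Inf`), `frequencies_hz`, `grid_size`.
#' @export
ein_spectrum <- function(fit, grid_size = 4096, tr_seconds = 1) {
  a <- fit$coefficients
  stopifnot(grid_size >= 2, grid_size >= length(a))
  padded <- c(a, rep(0, grid_size - length(a)))
  h2 <- Mod(stats::fft(padded))^2
  # bins whose response is negligible relative to the peak are treated as
  # exact zeros (the FFT of e.g. taps (1, 1) leaves ~1e-32 at the null)
  tol <- max(h2) * .Machine$double.eps^1.5
  values <- rep(Inf, grid_size)
  finite <- h2 > tol & max(h2) > 0
  values[finite] <- fit$noise_variance / h2[finite]
  structure(
    list(values = values,
         frequencies_hz = (seq_len(grid_size) - 1) / (grid_size * tr_seconds),
         grid_size = as.integer(grid_size)),
    class = "ein_spectrum"
  )
}

#' Water-filling capacity over a discrete equivalent-input-noise spectrum
#'
#' Sorts the finite spectrum values ascending and iterates the candidate
#' water level `lambda_m = (N + sum of the m smallest values) / m` upward in
#' `m`; the active set is the largest `m` with `lambda_m` above the m-th
#' sorted value. By construction the active bins then absorb exactly the
#' unit sender power: `(1/N) * sum(lambda - S) = 1`. Capacity is
#' `(2N)^{-1} * sum(log(lambda / S))` over the active bins.
#'
#' @param spectrum an [ein_spectrum()] (or list with `values`).
#' @param log_base `"bits"` (log base 2, the default reporting unit) or
#'   `"nats"` (natural log).
#' @return object of class `capacity_result`: list with `capacity`,
#'   `water_level`, `active_bins`, `grid_size`, `log_base`.
#' @export
water_fill <- function(spectrum, log_base = c("bits", "nats")) {
  log_base <- match.arg(log_base)
  S <- spectrum$values
  N <- length(S)
  if (N < 1) stop("empty spectrum")
  s_sorted <- sort(S[is.finite(S)])
  nf <- length(s_sorted)
  if (nf == 0L) {
    return(structure(
      list(capacity = 0, water_level = NA_real_, active_bins = 0L,
           grid_size = as.integer(N), log_base = log_base),
      class = "capacity_result"
    ))
  }
  cum <- cumsum(s_sorted)
  m_seq <- seq_len(nf)
  lambda_seq <- (N + cum) / m_seq
  # lambda_1 = N + S(1) > S(1) always: the active set is never empty
  active <- lambda_seq > s_sorted
  stopifnot(active[1])
  m <- max(which(active))
  lambda <- lambda_seq[m]
  cap_nats <- sum(log(lambda / s_sorted[seq_len(m)])) / (2 * N)
  structure(
    list(capacity = if (log_base == "bits") cap_nats / log(2) else cap_nats,
         water_level = lambda, active_bins = as.integer(m),
         grid_size = as.integer(N), log_base = log_base),
    class = "capacity_result"
  )
}

#' Channel capacity of a fitted FIR/AWGN channel
#'
#' Composes [ein_spectrum()] and [water_fill()]: the capacity of the fitted
#' channel under a unit power constraint on the (standardized) sender.
#' Scale-invariant: multiplying the taps and the noise standard deviation by
#' the same constant leaves the capacity unchanged.
#'
#' @inheritParams ein_spectrum
#' @inheritParams water_fill
#' @return a `capacity_result` (capacity 0 for an all-zero tap vector).
#' @examples
#' f <- structure(list(coefficients = 0.6, noise_variance = 0.64),
#'                class = "channel_fit")
#' channel_capacity(f, log_base = "nats")$capacity  # -0.5 * log(1 - 0.6^2)
#' @export
channel_capacity <- function(fit, grid_size = 4096,
                             log_base = c("bits", "nats"), tr_seconds = 1) {
  water_fill(ein_spectrum(fit, grid_size, tr_seconds), log_base = log_base)
}

#' Closed-form capacity of a one-tap channel at a given correlation
#'
#' For a standardized sender/receiver pair with sample correlation `r >= 0`,
#' the order-1 fit gives tap `r` and noise `1 - r^2`; the spectrum is flat
#' and water-filling reduces to `-0.5 * log(1 - r^2)`. Used as an analytic
#' reference for the numerical estimator.
#'
#' @param correlation value in `[0, 1)`.
#' @param log_base `"bits"` or `"nats"`.
#' @return nonnegative capacity.
#' @export
capacity_closed_form_one_tap <- function(correlation,
                                         log_base = c("bits", "nats")) {
  log_base <- match.arg(log_base)
  if (any(correlation < 0) || any(correlation >= 1)) {
    stop("correlation must lie in [0, 1)")
  }
  cap <- -0.5 * log(1 - correlation^2)
  if (log_base == "bits") cap / log(2) else cap
}
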