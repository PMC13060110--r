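#' Fit the nonnegative FIR channel of one window at a fixed order
#'
#' Standardizes the receiver and each lagged sender column to zero mean and
#' unit RMS, then solves the nonnegative least-squares problem
#' `min ||X a - y||^2, a >= 0` (Lawson-Hanson active set via
#' [pracma::lsqnonneg()]). The maximum-likelihood noise power is the mean
#' squared residual. An all-zero solution (e.g. for an anticorrelated pair)
#' is a valid fit meaning "no positive channel"; its capacity is zero.
#'
#' @param segment a [window_segment()].
#' @param order number of FIR taps, >= 1.
#' @param truncate passed to [build_convolution_matrix()].
#' @return object of class `channel_fit`: list with `order`, `coefficients`
#'   (length-`order`, all >= 0), `noise_variance`, `residuals`, `n_effective`
#'   (rows actually regressed), `fitted` (predicted standardized receiver) and
#'   `pcorr` (correlation of observed and predicted receiver; 0 for an
#'   all-zero fit).
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 0.8 * x + rnorm(100, sd = 0.6)
#' fit_channel(window_segment(x, y), order = 1)$coefficients
#' @export
fit_channel <- function(segment, order, truncate = TRUE) {
  des <- build_convolution_matrix(segment, order, truncate = truncate)
  y <- standardize(des$y)
  a <- if (order == 1L) {
    # single standardized column: NNLS solution is max(r, 0) in closed form
    max(sum(des$X[, 1] * y) / length(y), 0)
  } else {
    pracma::lsqnonneg(des$X, y)$x
  }
  a <- pmax(as.numeric(a), 0)
  fitted <- as.numeric(des$X %*% a)
  resid <- y - fitted
  sigma2 <- mean(resid^2)
  pcorr <- if (all(a == 0) || stats::sd(fitted) == 0) {
    0
  } else {
    stats::cor(y, fitted)
  }
  structure(
    list(order = as.integer(order), coefficients = a,
         noise_variance = sigma2, residuals = resid,
         n_effective = length(y), fitted = fitted, pcorr = pcorr,
         criterion_value = NA_real_),
    class = "channel_fit"
  )
}

#' Order-selection configuration
#'
#' @param criterion one of `"AICc"`, `"AIC"`, `"BIC"`.
#' @param k_max largest candidate order; must satisfy `k_max < n - 2` for the
#'   windows it is applied to. The default `NULL` resolves per window to
#'   `min(8, floor(n / 10))` (clamped to at least 1), which keeps the
#'   regression comfortably overdetermined.
#' @return list of class `order_config`.
#' @export
order_config <- function(criterion = c("AICc", "AIC", "BIC"), k_max = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(k_max)) stopifnot(k_max >= 1)
  structure(list(criterion = criterion, k_max = k_max),
            class = "order_config")
}

# Gaussian-regression information criterion for a fitted window.
# k counts FIR taps only; the noise variance is shared by every candidate so
# leaving it out does not change the ranking.
information_criterion <- function(sigma2, n, k, criterion) {
  ll_term <- n * log(max(sigma2, .Machine$double.xmin))
  switch(criterion,
    AIC  = ll_term + 2 * k,
    BIC  = ll_term + k * log(n),
    AICc = ll_term + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  )
}

#' Select the channel order of one window by information criterion
#'
#' Fits every order `1 ... k_max`, scores each with the configured criterion
#' computed from the Gaussian log-likelihood of its residuals, and returns
#' the fit minimizing the criterion. Ties break toward the smaller order
#' (parsimony). The selected order is the window's connection duration in
#' TR units.
#'
#' @param segment a [window_segment()].
#' @param config an [order_config()].
#' @param truncate passed to [fit_channel()].
#' @return the winning `channel_fit`, with `criterion_value` filled in and a
#'   `criterion_curve` attribute holding the score of every candidate order.
#' @export
select_order <- function(segment, config = order_config(), truncate = TRUE) {
  n <- segment$n
  k_max <- config$k_max
  if (is.null(k_max)) k_max <- max(1L, min(8L, n %/% 10L))
  if (k_max >= n - 2) {
    stop("k_max must satisfy k_max < n - 2 (got k_max = ", k_max,
         ", n = ", n, ")", call. = FALSE)
  }
  scores <- rep(NA_real_, k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fit <- fit_channel(segment, k, truncate = truncate)
    fits[[k]] <- fit
    scores[k] <- information_criterion(fit$noise_variance, fit$n_effective,
                                       k, config$criterion)
  }
  best <- which.min(scores)   # first minimum: ties go to the smaller order
  out <- fits[[best]]
  out$criterion_value <- scores[best]
  attr(out, "criterion_curve") <- scores
  out
}
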