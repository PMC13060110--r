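#' Capacity vs prediction-correlation dispersion by connection duration
#'
#' At connection duration 1 TR (one-tap channel) the capacity is a
#' deterministic, monotonically increasing function of the
#' prediction-correlation: `C = -0.5 * log(1 - pcorr^2)`. For longer
#' durations the relationship disperses, because capacity also depends on
#' the spectral shape of the fitted taps. This diagnostic quantifies the
#' dispersion per duration as the squared Pearson correlation between the
#' observed capacity and the order-1 capacity-equivalent of p-corr (the
#' closed form above, a monotone recoding that makes duration 1 exactly
#' deterministic). Values near 1 mean capacity is reducible to p-corr at
#' that duration; smaller values mean capacity carries extra information
#' about temporally sustained transfer.
#'
#' @param capacity numeric vector of window capacities.
#' @param pcorr numeric vector of window prediction-correlations.
#' @param duration_trs integer vector of window connection durations.
#' @param min_samples durations with fewer usable windows are dropped.
#' @return named numeric vector of R-squared values, one per duration
#'   present (names = duration in TRs).
#' @export
capacity_pcorr_r2 <- function(capacity, pcorr, duration_trs,
                              min_samples = 10) {
  stopifnot(length(capacity) == length(pcorr),
            length(capacity) == length(duration_trs))
  ok <- is.finite(capacity) & is.finite(pcorr) & pcorr > 0 & pcorr < 1
  out <- c()
  for (d in sort(unique(duration_trs[ok]))) {
    sel <- ok & duration_trs == d
    if (sum(sel) < min_samples) next
    equiv <- -0.5 * log(1 - pcorr[sel]^2)
    out[as.character(d)] <- stats::cor(capacity[sel], equiv)^2
  }
  out
}
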