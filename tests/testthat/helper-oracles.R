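# Independent reference implementations used to validate the estimators.
# These deliberately use different algorithms than the package code.

# Water-filling by bisection on the water level: find lambda such that
# sum((lambda - S)+) = N, then integrate log(lambda / S) over active bins.
oracle_water_fill <- function(S, N = length(S)) {
  Sf <- S[is.finite(S)]
  if (length(Sf) == 0) return(0)
  lo <- min(Sf)
  hi <- min(Sf) + N + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(pmax(mid - Sf, 0)) > N) hi <- mid else lo <- mid
  }
  lambda <- (lo + hi) / 2
  sum(log(lambda / Sf[Sf < lambda])) / (2 * N)
}

# Exact one-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (left tail: P(W <= w_obs) for W = sum of positive ranks).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% ranks
  mean(w_all <= w_obs)
}

# Benjamini-Hochberg q-values computed directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Planted task/rest paired-sample design at the stated effect size:
# 4 of n_pairs pairs have task = rest + delta, all values around mu0.
planted_task_rest_samples <- function(seed, n_pairs = 20, n_units = 30,
                                      n_planted = 4, mu0 = 1, sigma = 0.2,
                                      delta = 1.5 * 0.2) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    shift <- if (p <= n_planted) delta else 0
    data.frame(unit_id = sprintf("s%02d", seq_len(n_units)),
               pair = sprintf("pair%02d", p),
               task_value = rnorm(n_units, mu0 + shift, sigma),
               rest_value = rnorm(n_units, mu0, sigma),
               stringsAsFactors = FALSE)
  }))
}

# Sliding-capacity asymmetry samples for a list of 2-region scans.
asymmetry_samples <- function(scans, window = 50, step = 25, k_max = 2,
                              grid = 512) {
  cfg <- order_config("BIC", k_max = k_max)
  do.call(rbind, lapply(scans, function(ts) {
    plan <- plan_windows(ncol(ts$values), window, step)
    f <- sliding_capacity(ts$values[1, ], ts$values[2, ], plan, cfg, grid,
                          "bits", ts$tr_seconds)
    b <- sliding_capacity(ts$values[2, ], ts$values[1, ], plan, cfg, grid,
                          "bits", ts$tr_seconds)
    data.frame(scan_id = ts$scan_id,
               forward_mean = mean(f$capacity, na.rm = TRUE),
               backward_mean = mean(b$capacity, na.rm = TRUE))
  }))
}

make_fit <- function(coefficients, noise_variance) {
  structure(list(coefficients = coefficients,
                 noise_variance = noise_variance),
            class = "channel_fit")
}
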