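test_that("standardization gives zero mean and unit population RMS", {
  expect_equal(standardize(c(1, -1)), c(1, -1))
  expect_equal(standardize(c(2, 0)), c(1, -1))
  out <- standardize(c(3, 1, 2))
  expect_equal(mean(out), 0)
  expect_equal(sqrt(mean(out^2)), 1)
  # proportional to (1, -1, 0): subtract mean 2, divide by RMS sqrt(2/3)
  expect_equal(out, c(1, -1, 0) / sqrt(2 / 3))
  set.seed(1)
  for (n in c(2, 17, 100)) {
    z <- standardize(rnorm(n, mean = 5, sd = 3))
    expect_equal(mean(z), 0)
    expect_equal(mean(z^2), 1)
  }
})

test_that("constant input is a degenerate-signal error", {
  expect_error(standardize(rep(4, 10)), "degenerate")
  expect_error(standardize(5), "at least 2")
})

test_that("convolution matrix lags the sender and honors the lookback", {
  seg <- window_segment(c(2, 3), c(0, 0), lookback = 1)
  raw <- build_convolution_matrix(seg, 2, standardize_columns = FALSE)
  expect_equal(raw$X, rbind(c(2, 1), c(3, 2)))
  expect_equal(raw$rows_dropped, 0)

  # order 1: single column equals the standardized sender
  seg1 <- window_segment(c(1, 5, 3), c(0, 1, 0))
  d1 <- build_convolution_matrix(seg1, 1)
  expect_equal(d1$X[, 1], standardize(c(1, 5, 3)))

  # no lookback, order 2, truncation: lagged pairs from rows t = 2..4
  seg2 <- window_segment(c(1, 2, 3, 4), c(9, 8, 7, 6))
  d2 <- build_convolution_matrix(seg2, 2, standardize_columns = FALSE)
  expect_equal(d2$X, cbind(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(d2$rows_dropped, 1)
  expect_equal(d2$y, c(8, 7, 6))
  expect_error(build_convolution_matrix(seg2, 2, truncate = FALSE),
               "too early")
})

test_that("order-1 fit matches the max(r, 0) closed form and the solver", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    y <- runif(1, -1, 1) * x + rnorm(n, sd = runif(1, 0.2, 2))
    seg <- window_segment(x, y)
    fit <- fit_channel(seg, 1)
    xs <- standardize(x); ys <- standardize(y)
    r <- mean(xs * ys)
    a0 <- max(r, 0)
    expect_equal(fit$coefficients, a0, tolerance = 1e-10)
    expect_equal(fit$noise_variance, 1 - a0 * (2 * r - a0),
                 tolerance = 1e-8)
    # agree with the generic NNLS solver route
    num <- pracma::lsqnonneg(matrix(xs, ncol = 1), ys)$x
    expect_equal(fit$coefficients, num, tolerance = 1e-8)
  }
})

test_that("perfect, anticorrelated and r = 0.6 channels fit as expected", {
  set.seed(7)
  x <- rnorm(80)
  same <- fit_channel(window_segment(x, x), 1)
  expect_equal(same$coefficients, 1)
  expect_lt(same$noise_variance, 1e-20)

  anti <- fit_channel(window_segment(x, -x), 1)
  expect_equal(anti$coefficients, 0)
  expect_equal(anti$noise_variance, 1)
  expect_equal(anti$pcorr, 0)

  # construct a pair with sample correlation exactly 0.6
  e <- rnorm(80)
  e <- standardize(residuals(lm(e ~ x)))
  xs <- standardize(x)
  y <- 0.6 * xs + sqrt(1 - 0.36) * e
  fit <- fit_channel(window_segment(xs, y), 1)
  expect_equal(fit$coefficients, 0.6, tolerance = 1e-10)
  expect_equal(fit$noise_variance, 0.64, tolerance = 1e-10)
  expect_equal(fit$pcorr, 0.6, tolerance = 1e-10)
})

test_that("coefficients are nonnegative and noise is bounded by unit power", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(15:80, 1)
    k <- sample(1:4, 1)
    x <- cumsum(rnorm(n + k))   # colored sender
    y <- rnorm(n)
    seg <- window_segment(x[(k + 1):(n + k)], y, lookback = x[1:k])
    fit <- fit_channel(seg, k)
    expect_true(all(fit$coefficients >= 0))
    expect_gte(fit$noise_variance, 0)
    expect_lte(fit$noise_variance, 1 + 1e-12)
    expect_equal(fit$noise_variance, mean(fit$residuals^2))
  }
})

test_that("information criteria take their standard Gaussian forms", {
  ic <- capconn:::information_criterion
  s2 <- 0.5; n <- 100; k <- 3
  expect_equal(ic(s2, n, k, "AIC"), n * log(s2) + 2 * k)
  expect_equal(ic(s2, n, k, "BIC"), n * log(s2) + k * log(n))
  expect_equal(ic(s2, n, k, "AICc"),
               n * log(s2) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
})

test_that("order selection recovers the true order and stays parsimonious", {
  # one strong tap at high SNR: order 1 selected in >= 90% of replicates
  sel1 <- vapply(1:100, function(s) {
    ts <- simulate_pair(0.9, 0.2, 200, seed = s)
    select_order(window_segment(ts$values[1, ], ts$values[2, ]),
                 order_config("BIC", k_max = 4))$order
  }, integer(1))
  expect_gte(mean(sel1 == 1L), 0.9)

  # two equal taps at high SNR: BIC picks order 2 in the majority
  sel2 <- vapply(1:60, function(s) {
    ts <- simulate_pair(c(0.5, 0.5), 0.2, 200, seed = 1000 + s)
    select_order(window_segment(ts$values[1, ], ts$values[2, ]),
                 order_config("BIC", k_max = 4))$order
  }, integer(1))
  expect_gt(mean(sel2 == 2L), 0.5)

  # pure-noise receiver: order 1 preferred more often than any higher order
  seln <- vapply(1:80, function(s) {
    set.seed(2000 + s)
    select_order(window_segment(rnorm(100), rnorm(100)),
                 order_config("BIC", k_max = 4))$order
  }, integer(1))
  tab <- tabulate(seln, 4)
  expect_true(all(tab[1] > tab[2:4]))
})

test_that("k_max must leave the AICc denominator positive", {
  seg <- window_segment(rnorm(10), rnorm(10))
  expect_error(select_order(seg, order_config("AICc", k_max = 8)), "k_max")
})

test_that("coefficient error shrinks as the window grows", {
  rmse_at <- function(n) {
    mean(vapply(1:30, function(s) {
      ts <- simulate_pair(c(0.5, 0.3), 0.5, n, seed = 3000 + s)
      fit <- fit_channel(window_segment(ts$values[1, ], ts$values[2, ]), 2)
      sx <- sqrt(mean(scale(ts$values[1, ], scale = FALSE)^2))
      sy <- sqrt(mean(scale(ts$values[2, ], scale = FALSE)^2))
      sqrt(mean((fit$coefficients * sy / sx - c(0.5, 0.3))^2))
    }, numeric(1)))
  }
  errs <- vapply(c(64, 256, 1024), rmse_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
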