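test_that("BH q-values match the brute-force definition and bound p", {
  p <- c(0.003, 0.04, 0.019, 0.7, 0.011)
  q_pkg <- p.adjust(p, method = "BH")
  expect_equal(q_pkg, oracle_bh(p))
  # hand-worked: sorted p * 5 / rank, cumulative minima from the top
  expect_equal(q_pkg, c(0.015, 0.05, 0.031666666666666666, 0.7, 0.0275),
               tolerance = 1e-12)
  expect_true(all(q_pkg >= p))
})

test_that("identical task and rest values yield no discoveries", {
  samples <- data.frame(unit_id = rep(sprintf("s%d", 1:10), 3),
                        pair = rep(c("a", "b", "c"), each = 10),
                        task_value = rep(runif(10, 0.5, 1.5), 3))
  samples$rest_value <- samples$task_value
  rep <- suppressWarnings(sensitivity_test(samples))
  expect_length(rep$significant_set, 0)
})

test_that("sensitivity test recovers planted pairs with FDR control", {
  hits <- fps <- numeric(40)
  for (s in 1:40) {
    out <- sensitivity_test(planted_task_rest_samples(s))
    hits[s] <- sum(out$significant_set %in% sprintf("pair%02d", 1:4))
    fps[s] <- length(out$significant_set) - hits[s]
  }
  expect_gt(mean(hits), 3.5)
  expect_lt(mean(fps), 0.3)
  # all-null design: any-discovery rate small
  anyd <- vapply(1:120, function(s) {
    out <- sensitivity_test(planted_task_rest_samples(5000 + s,
                                                      n_planted = 0))
    length(out$significant_set) > 0
  }, logical(1))
  expect_lte(mean(anyd), 0.08)
})

test_that("the CV screen excludes unstable and undefined pairs", {
  set.seed(71)
  base <- planted_task_rest_samples(1, n_pairs = 3, n_planted = 0)
  # pair03 made highly variable across units
  sel <- base$pair == "pair03"
  base$task_value[sel] <- rnorm(30, 1, 0.8)
  rep <- sensitivity_test(base, cv_threshold = 0.30)
  expect_true("pair03" %in% rep$excluded)
  expect_false("pair01" %in% rep$excluded)
})

test_that("signed-rank left-tailed p matches exhaustive enumeration", {
  set.seed(73)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    asym <- abs(rnorm(n, 0.3, 0.2))
    v <- runif(1, 0.2, 0.6)
    samples <- data.frame(scan_id = seq_len(n), forward_mean = asym,
                          backward_mean = 0)
    # same statistic as specificity_test: wilcoxon of (asym - v), left tail
    p_pkg <- wilcox.test(asym, mu = v, alternative = "less",
                         exact = TRUE)$p.value
    expect_equal(p_pkg, oracle_signed_rank_p(asym - v), tolerance = 1e-12)
  }
})

test_that("specificity test is calibrated on boundary and null designs", {
  # asymmetries scattered symmetrically around the variability: p in the
  # central region, no rejection
  set.seed(89)
  f <- c(1.0, 1.2, 0.9, 1.1, 1.05, 0.95, 1.15, 0.85, 1.0, 1.1)
  v <- sd(f - sd(f) / 2)       # = sd(f), the eventual variability
  jitter <- rep(c(-1, 1), 5) * runif(10, 0.001, 0.003)
  sams <- data.frame(scan_id = 1:10, forward_mean = f,
                     backward_mean = f - (v + jitter))
  rep <- specificity_test(sams)
  expect_false(rep$reject)
  expect_gt(rep$p_value, 0.2)
  expect_lt(rep$p_value, 0.8)
  expect_error(specificity_test(sams[1:4, ]), "at least 6")
})

test_that("specificity pipeline separates bilateral null from directed", {
  null_p <- vapply(1:5, function(s) {
    scans <- simulate_bilateral_null(12, 250, 0.8, 0.6, 0.35, 0.5,
                                     seed = 100 * s)
    specificity_test(asymmetry_samples(scans))$p_value
  }, numeric(1))
  expect_true(all(null_p < 0.02))
  dir_p <- vapply(1:5, function(s) {
    scans <- simulate_directed_pairs(12, 250, c(0, 0.8), 0.6, 0.35, 0.5,
                                     seed = 9000 + 100 * s)
    specificity_test(asymmetry_samples(scans))$p_value
  }, numeric(1))
  expect_true(all(dir_p > 0.5))
})

test_that("window bootstrap is exact on identity and seed-reproducible", {
  set.seed(79)
  a <- lapply(1:4, function(i) rnorm(30))
  same <- bootstrap_window_correlation(a, a, n_boot = 200, seed = 5)
  expect_true(all(abs(same$replicates - 1) < 1e-12))
  b <- lapply(a, function(v) v + rnorm(30))
  r1 <- bootstrap_window_correlation(a, b, n_boot = 300, seed = 7)
  r2 <- bootstrap_window_correlation(a, b, n_boot = 300, seed = 7)
  expect_identical(r1$replicates, r2$replicates)
  # replicate mean close to the plug-in correlation at SNR 1
  expect_lt(abs(r1$mean - r1$plug_in), 0.1)
})

test_that("window bootstrap CI covers zero for independent series", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    a <- lapply(1:3, function(i) rnorm(25))
    b <- lapply(1:3, function(i) rnorm(25))
    ci <- bootstrap_window_correlation(a, b, n_boot = 200, seed = s)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("matrix bootstrap tracks planted shared structure", {
  set.seed(83)
  off <- function(m) { diag(m) <- 0; m }
  shared <- off(matrix(runif(36), 6))
  make_mats <- function(noise_sd) {
    lapply(1:8, function(i) off(shared + matrix(rnorm(36, sd = noise_sd), 6)))
  }
  ident <- bootstrap_matrix_correlation(make_mats(0), make_mats(0),
                                        n_boot = 150, seed = 1)
  expect_true(all(abs(ident$replicates - 1) < 1e-12))
  # correlation rises as the shared structure's share of variance grows
  means <- vapply(c(2, 0.7, 0.2), function(ns) {
    bootstrap_matrix_correlation(make_mats(ns), make_mats(ns),
                                 n_boot = 150, seed = 2)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # permuted-entry control: CI covers zero
  a <- make_mats(0.3)
  b <- lapply(a, function(m) {
    v <- m[row(m) != col(m)]
    out <- m; out[row(m) != col(m)] <- sample(v); out
  })
  ctrl <- bootstrap_matrix_correlation(a, b, n_boot = 200, seed = 3)
  expect_true(ctrl$ci[1] <= 0 && 0 <= ctrl$ci[2])
})
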