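#' Cluster window-resolved connectivity matrices into brain states
#'
#' Pools vectorized directed connectivity matrices (one row per window) and
#' clusters them with k-means (Lloyd iterations, k-means++ seeding, best of
#' `n_init` seeded initializations per `k`). The number of states is chosen
#' on the within-cluster-sum-of-squares (WCSS) curve by the elbow rule:
#' with the curve normalized to the unit square, the candidate `k`
#' maximizing the discrete second difference wins; ties go to the smaller
#' `k`. Features are used as-is (no per-column scaling): capacity entries
#' share units across pairs.
#'
#' @param features numeric matrix, windows x features (directed off-diagonal
#'   entries), or a data.frame coercible to one.
#' @param k_range candidate numbers of states (default `1:10`).
#' @param n_init random initializations per `k` (default 6).
#' @param seed integer seed; results are reproducible bit-exactly.
#' @param iter_max Lloyd iteration cap per run.
#' @return object of class `state_solution`: list with `k`, `centroids`
#'   (k x D), `labels` (length W, in `1..k`), `wcss_curve` (named by `k`),
#'   `chosen_by = "elbow-second-difference"`.
#' @export
fit_states <- function(features, k_range = 1:10, n_init = 6, seed = 1,
                       iter_max = 100) {
  features <- as.matrix(features)
  W <- nrow(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > W) stop("k_range contains k > number of windows")
  if (W < 2 * max(k_range)) {
    stop("need at least 2 windows per candidate state")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  wcss <- numeric(length(k_range))
  best_fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- NULL
    for (init in seq_len(n_init)) {
      set.seed(seed + 1000L * i + init)
      fit <- .kmeans_once(features, k, iter_max)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    wcss[i] <- best$tot.withinss
    best_fits[[i]] <- best
  }
  names(wcss) <- k_range
  k_best <- k_range[.elbow_index(k_range, wcss)]
  sol <- best_fits[[match(k_best, k_range)]]
  structure(
    list(k = k_best, centroids = sol$centers,
         labels = as.integer(sol$cluster), wcss_curve = wcss,
         chosen_by = "elbow-second-difference"),
    class = "state_solution"
  )
}

# One seeded k-means run: k-means++ centers, then Lloyd iterations via
# stats::kmeans. k = 1 reduces to the grand mean.
.kmeans_once <- function(x, k, iter_max) {
  if (k == 1L) {
    centre <- matrix(colMeans(x), 1)
    return(list(centers = centre,
                cluster = rep(1L, nrow(x)),
                tot.withinss = sum(sweep(x, 2, centre[1, ])^2)))
  }
  centers <- .kmeanspp_centers(x, k)
  fit <- tryCatch(
    stats::kmeans(x, centers = centers, iter.max = iter_max,
                  algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
  )
  if (is.null(fit)) {
    # empty-cluster failure: fall back to a fresh random-row start
    fit <- stats::kmeans(x, centers = k, iter.max = iter_max)
  }
  fit
}

# k-means++ seeding: first center uniform over rows, each further center
# drawn with probability proportional to squared distance to the nearest
# chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    idx[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE]
}

# Elbow as the maximum second difference of the log-WCSS curve (discrete
# curvature on the ratio scale, so a halving followed by a plateau beats an
# early large absolute drop); first index on ties (smaller k). Curves where
# clustering never removes a substantial share of the total variance
# (min WCSS > 70% of WCSS at k = 1) have no elbow and return the smallest k.
.elbow_index <- function(k_range, wcss) {
  j <- length(k_range)
  if (j < 3) return(1L)
  if (min(wcss) > 0.7 * wcss[1]) return(1L)
  ys <- log(pmax(wcss, max(wcss) * 1e-12))
  # uniform k spacing assumed for the discrete curvature
  d2 <- ys[1:(j - 2)] - 2 * ys[2:(j - 1)] + ys[3:j]
  which.max(d2) + 1L
}

#' Align the states of one solution to a reference by centroid permutation
#'
#' Exhaustively searches all `k!` relabelings of `other`'s states and keeps
#' the one maximizing the summed Pearson correlation between matched
#' centroid vectors (used to align, e.g., calcium-derived states to
#' fMRI-derived states). Guarded to `k <= 8` (40320 permutations).
#'
#' @param reference,other `state_solution` objects with equal `k` and
#'   feature dimension.
#' @return list with `permutation` (`permutation[i]` = state of `other`
#'   matched to reference state `i`), `pair_correlations`, `total`,
#'   `relabelled` (other's labels rewritten into reference numbering).
#' @export
align_centroids <- function(reference, other) {
  stopifnot(inherits(reference, "state_solution"),
            inherits(other, "state_solution"),
            reference$k == other$k,
            ncol(reference$centroids) == ncol(other$centroids))
  k <- reference$k
  if (k > 8) stop("exhaustive centroid alignment guarded to k <= 8")
  perms <- .permutations(k)
  best_total <- -Inf
  best_perm <- NULL
  cors <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cors[i, j] <- stats::cor(reference$centroids[i, ], other$centroids[j, ])
    }
  }
  for (p in seq_len(nrow(perms))) {
    total <- sum(cors[cbind(seq_len(k), perms[p, ])])
    if (total > best_total) {
      best_total <- total
      best_perm <- perms[p, ]
    }
  }
  relabel <- integer(k)
  relabel[best_perm] <- seq_len(k)   # other-state s becomes reference state
  list(permutation = best_perm,
       pair_correlations = cors[cbind(seq_len(k), best_perm)],
       total = best_total,
       relabelled = relabel[other$labels])
}

# All permutations of 1..k as rows (k! x k), lexicographic.
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (s in seq_len(nrow(sub))) {
      out[r, ] <- c(first, rest[sub[s, ]])
      r <- r + 1L
    }
  }
  out
}

#' Correlation of two aligned state time courses
#'
#' Pearson correlation of two integer label sequences over shared windows
#' (after centroid alignment), treated as numeric time courses. Constant
#' sequences are undefined and return `NA` with a warning.
#'
#' @param labels_a,labels_b integer vectors of equal length.
#' @return correlation in `[-1, 1]` or `NA`.
#' @export
state_timecourse_correlation <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  if (stats::sd(labels_a) == 0 || stats::sd(labels_b) == 0) {
    warning("constant state sequence: correlation undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(labels_a), as.numeric(labels_b))
}
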