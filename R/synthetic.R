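#' Labelled multi-region time-series container
#'
#' @param values numeric matrix, regions x time.
#' @param roi_labels character vector of region names (default `ROI1..R`).
#' @param tr_seconds sampling interval in seconds.
#' @param scan_id,subject_id,condition optional metadata strings.
#' @return object of class `roi_ts`.
#' @export
roi_timeseries <- function(values, roi_labels = NULL, tr_seconds = 1,
                           scan_id = "scan1", subject_id = NA_character_,
                           condition = NA_character_) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values are not allowed in the analyzed span")
  if (nrow(values) < 2) stop("need at least 2 regions")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(nrow(values)))
  stopifnot(length(roi_labels) == nrow(values), tr_seconds > 0)
  rownames(values) <- roi_labels
  structure(
    list(values = values, roi_labels = roi_labels, tr_seconds = tr_seconds,
         scan_id = scan_id, subject_id = subject_id, condition = condition),
    class = "roi_ts"
  )
}

# FIR filter with zero pre-history: y_t = sum_j taps[j+1] * x_{t-j}.
.fir_apply <- function(x, taps) {
  k <- length(taps)
  xp <- c(rep(0, k - 1), x)
  out <- numeric(length(x))
  for (j in seq_len(k)) {
    out <- out + taps[j] * xp[(k - j + 1):(k - j + length(x))]
  }
  out
}

# Sender signal generators for the channel simulations.
.make_sender <- function(n, model = c("white", "ar1", "bandlimited"),
                         ar_coef = 0.5, passband = c(0.01, 0.1),
                         tr_seconds = 1) {
  model <- match.arg(model)
  if (model == "white") return(stats::rnorm(n))
  if (model == "ar1") {
    x <- as.numeric(stats::arima.sim(list(ar = ar_coef), n))
    return(x / stats::sd(x))
  }
  # band-limited Gaussian via hard FFT mask
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- (seq_len(n) - 1) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)   # fold to [0, Nyquist]
  keep <- freq >= passband[1] & freq <= passband[2]
  keep[1] <- FALSE
  f[!keep] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a coupled sender/receiver pair from the FIR channel model
#'
#' The receiver is the FIR convolution of the sender with nonnegative taps
#' plus independent zero-mean white Gaussian noise — exactly the generative
#' model the estimator assumes. The sender is white Gaussian by default;
#' AR(1) and band-limited variants probe robustness to colored senders.
#'
#' @param taps nonnegative numeric vector of true FIR coefficients.
#' @param noise_sd receiver noise standard deviation (>= 0).
#' @param n_timepoints series length `T` (> 10 * length(taps)).
#' @param sender_model `"white"`, `"ar1"` or `"bandlimited"`.
#' @param ar_coef AR(1) coefficient when `sender_model = "ar1"`.
#' @param passband Hz band when `sender_model = "bandlimited"`.
#' @param tr_seconds sampling interval.
#' @param seed integer seed (bit-reproducible).
#' @param scan_id scan label.
#' @return a 2-region `roi_ts` with regions `"sender"`, `"receiver"` and a
#'   `ground_truth` attribute (taps, noise_sd, seed).
#' @export
simulate_pair <- function(taps, noise_sd, n_timepoints,
                          sender_model = "white", ar_coef = 0.5,
                          passband = c(0.01, 0.1), tr_seconds = 1,
                          seed = 1, scan_id = "sim_pair") {
  stopifnot(all(taps >= 0), noise_sd >= 0,
            n_timepoints > 10 * length(taps))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- .make_sender(n_timepoints, sender_model, ar_coef, passband, tr_seconds)
  y <- .fir_apply(x, taps) + stats::rnorm(n_timepoints, sd = noise_sd)
  ts <- roi_timeseries(rbind(x, y), c("sender", "receiver"),
                       tr_seconds, scan_id)
  attr(ts, "ground_truth") <- list(taps = taps, noise_sd = noise_sd,
                                   seed = seed)
  ts
}

#' Simulate bilateral null scans with no true directionality
#'
#' Each scan drives two homotopic regions from one shared latent signal
#' filtered by identical taps, plus independent per-region noise; the two
#' directions are statistically exchangeable by construction, so any
#' estimated directional asymmetry is pure estimation noise. A per-scan
#' lognormal gain jitter on the shared drive creates genuine scan-to-scan
#' variability in coupling strength, emulating state differences between
#' sessions.
#'
#' @param n_scans number of scans (>= 6).
#' @param n_timepoints samples per scan.
#' @param taps shared-drive FIR taps (both regions identical).
#' @param noise_sd per-region independent noise SD.
#' @param gain_jitter_sd SD of the per-scan log-gain (0 = no jitter).
#' @param tr_seconds sampling interval.
#' @param seed integer seed.
#' @return list of `roi_ts` objects (regions `"L"`, `"R"`), one per scan.
#' @export
simulate_bilateral_null <- function(n_scans = 22, n_timepoints = 300,
                                    taps = 0.8, noise_sd = 0.6,
                                    gain_jitter_sd = 0.35,
                                    tr_seconds = 0.5, seed = 1) {
  stopifnot(n_scans >= 6, all(taps >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  scans <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    set.seed(seed + s)
    gain <- exp(stats::rnorm(1, sd = gain_jitter_sd))
    z <- stats::rnorm(n_timepoints)
    drive <- gain * .fir_apply(z, taps)
    left <- drive + stats::rnorm(n_timepoints, sd = noise_sd)
    right <- drive + stats::rnorm(n_timepoints, sd = noise_sd)
    scans[[s]] <- roi_timeseries(rbind(left, right), c("L", "R"),
                                 tr_seconds, scan_id = sprintf("scan%02d", s))
  }
  scans
}

#' Simulate a directed (one-way coupled) pair collection
#'
#' Counterpart of [simulate_bilateral_null()] for the alternative
#' hypothesis: coupling runs only sender -> receiver, through purely lagged
#' taps (default one-sample delay) so that the reverse regression finds no
#' channel with a white sender. Per-scan gain jitter as in the null.
#'
#' @inheritParams simulate_bilateral_null
#' @param taps FIR taps of the forward coupling; the default `c(0, 0.8)`
#'   is a pure one-TR delay.
#' @return list of 2-region `roi_ts` objects (regions `"L"`, `"R"`, coupling
#'   L -> R only).
#' @export
simulate_directed_pairs <- function(n_scans = 22, n_timepoints = 300,
                                    taps = c(0, 0.8), noise_sd = 0.6,
                                    gain_jitter_sd = 0.35,
                                    tr_seconds = 0.5, seed = 1) {
  stopifnot(n_scans >= 1, all(taps >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  scans <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    set.seed(seed + s)
    gain <- exp(stats::rnorm(1, sd = gain_jitter_sd))
    x <- stats::rnorm(n_timepoints)
    y <- gain * .fir_apply(x, taps) + stats::rnorm(n_timepoints, sd = noise_sd)
    scans[[s]] <- roi_timeseries(rbind(x, y), c("L", "R"),
                                 tr_seconds, scan_id = sprintf("scan%02d", s))
  }
  scans
}

#' Simulate a task/rest trial design and estimate per-unit capacity samples
#'
#' Emulates a blocked task paradigm with short trials: for every subject,
#' pair and trial, a 2-region trial series is generated; planted pairs
#' carry FIR coupling (scaled by `effect_size`) during task trials only,
#' all other pair/condition combinations are uncoupled noise. Each trial is
#' analyzed as a single window (trial-level fit, AICc order selection) and
#' trials are averaged within subject, yielding one paired
#' (task, rest) capacity sample per subject and pair — the input of
#' [sensitivity_test()].
#'
#' @param n_subjects number of subjects (pairing units).
#' @param n_pairs number of directed pairs.
#' @param planted_pairs integer indices of truly coupled pairs.
#' @param effect_size multiplier on the base coupling tap (0 = null design).
#' @param n_trials trials per condition per subject.
#' @param trial_len samples per trial (short-trial regime).
#' @param noise_sd receiver noise SD.
#' @param k_max largest candidate order for the trial fits.
#' @param grid_size DFT length for capacity.
#' @param seed integer seed.
#' @return data.frame with columns `unit_id`, `pair`, `task_value`,
#'   `rest_value` (subject-mean capacities, bits).
#' @export
simulate_task_rest <- function(n_subjects = 30, n_pairs = 20,
                               planted_pairs = 1:4, effect_size = 1,
                               n_trials = 4, trial_len = 16,
                               noise_sd = 0.8, k_max = 3, grid_size = 1024,
                               seed = 1) {
  stopifnot(all(planted_pairs %in% seq_len(n_pairs)), trial_len >= 8)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cfg <- order_config("AICc", k_max = k_max)
  base_tap <- 0.8
  rows <- vector("list", n_subjects * n_pairs)
  r <- 1L
  trial_capacity <- function(coupled) {
    x <- stats::rnorm(trial_len)
    y <- if (coupled) {
      effect_size * base_tap * x + stats::rnorm(trial_len, sd = noise_sd)
    } else {
      stats::rnorm(trial_len)
    }
    fit <- select_order(window_segment(x, y), cfg)
    channel_capacity(fit, grid_size)$capacity
  }
  for (subj in seq_len(n_subjects)) {
    for (p in seq_len(n_pairs)) {
      coupled <- p %in% planted_pairs && effect_size > 0
      task <- mean(vapply(seq_len(n_trials),
                          function(i) trial_capacity(coupled), numeric(1)))
      rest <- mean(vapply(seq_len(n_trials),
                          function(i) trial_capacity(FALSE), numeric(1)))
      rows[[r]] <- data.frame(unit_id = sprintf("subj%02d", subj),
                              pair = sprintf("pair%02d", p),
                              task_value = task, rest_value = rest,
                              stringsAsFactors = FALSE)
      r <- r + 1L
    }
  }
  do.call(rbind, rows)
}

#' Simulate window features drawn around planted state centroids
#'
#' Emits one feature row per window, sampled as an isotropic Gaussian
#' around its planted state centroid, plus the ground-truth labels — the
#' direct input for validating [fit_states()]. Centroids are auto-generated
#' (nonnegative, well separated) unless supplied.
#'
#' @param n_states number of planted states (>= 2).
#' @param n_features feature dimension (directed off-diagonal count).
#' @param windows_per_state rows per state.
#' @param separation typical between-centroid distance scale.
#' @param spread within-state (per-coordinate) SD.
#' @param centroids optional k x D matrix overriding auto-generation.
#' @param seed integer seed.
#' @return list with `features` (W x D matrix, rows shuffled), `labels`
#'   (planted state of each row) and `centroids`.
#' @export
simulate_state_sessions <- function(n_states = 4, n_features = 30,
                                    windows_per_state = 500,
                                    separation = 5, spread = 0.5,
                                    centroids = NULL, seed = 1) {
  stopifnot(n_states >= 2, spread >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(centroids)) {
    centroids <- matrix(stats::runif(n_states * n_features,
                                     0, separation),
                        n_states, n_features)
  }
  stopifnot(nrow(centroids) == n_states)
  W <- n_states * windows_per_state
  labels <- rep(seq_len(n_states), each = windows_per_state)
  features <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(W * ncol(centroids), sd = spread), W)
  ord <- sample.int(W)
  list(features = features[ord, , drop = FALSE], labels = labels[ord],
       centroids = centroids)
}

#' Simulate a multi-region session whose coupling switches between states
#'
#' Produces a full region x time series in which the directed coupling
#' matrix alternates among a small set of planted states over consecutive
#' spans. Each region carries its own white-noise base signal; receivers
#' add the FIR-filtered base signals of their senders according to the
#' active state's coupling matrix (entry `[i, j]` couples region i into
#' region j with a one-tap gain).
#'
#' @param coupling_states list of R x R nonnegative gain matrices with zero
#'   diagonal, one per state.
#' @param span_length samples per state span.
#' @param state_sequence integer vector of state indices over spans.
#' @param noise_sd per-region base noise SD.
#' @param tr_seconds sampling interval.
#' @param seed integer seed.
#' @return a `roi_ts` with a `ground_truth` attribute holding the span-wise
#'   state labels.
#' @export
simulate_switching_session <- function(coupling_states, span_length = 200,
                                       state_sequence = c(1, 2, 1, 2),
                                       noise_sd = 1, tr_seconds = 1,
                                       seed = 1) {
  R <- nrow(coupling_states[[1]])
  stopifnot(all(vapply(coupling_states,
                       function(m) all(dim(m) == R) && all(diag(m) == 0) &&
                         all(m >= 0), logical(1))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  total <- span_length * length(state_sequence)
  base <- matrix(stats::rnorm(R * total, sd = noise_sd), R)
  values <- base
  for (span in seq_along(state_sequence)) {
    idx <- ((span - 1) * span_length + 1):(span * span_length)
    cm <- coupling_states[[state_sequence[span]]]
    for (i in seq_len(R)) {
      for (j in seq_len(R)) {
        if (cm[i, j] > 0) {
          values[j, idx] <- values[j, idx] + cm[i, j] * base[i, idx]
        }
      }
    }
  }
  ts <- roi_timeseries(values, tr_seconds = tr_seconds,
                       scan_id = "sim_session")
  attr(ts, "ground_truth") <- list(state_sequence = state_sequence,
                                   span_length = span_length, seed = seed)
  ts
}
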