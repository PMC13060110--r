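#' Read a region-by-time series table from delimited text
#'
#' Accepts CSV/TSV with region labels as a header (time x region layout,
#' `orientation = "roi_cols"`) or as a first column (region x time layout,
#' `orientation = "roi_rows"`).
#'
#' @param path file path.
#' @param tr_seconds sampling interval in seconds (required; it is not
#'   stored in the table).
#' @param orientation `"roi_rows"` or `"roi_cols"`.
#' @param sep field separator (`","` or `"\t"`; guessed from the extension
#'   when `NULL`).
#' @param scan_id scan label (defaults to the file name without extension).
#' @return a `roi_ts` object.
#' @export
read_roi_timeseries <- function(path, tr_seconds,
                                orientation = c("roi_rows", "roi_cols"),
                                sep = NULL, scan_id = NULL) {
  orientation <- match.arg(orientation)
  if (missing(tr_seconds)) stop("tr_seconds is required")
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  if (is.null(scan_id)) scan_id <- sub("\\.[^.]*$", "", basename(path))
  if (orientation == "roi_cols") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
    values <- t(as.matrix(tab))
    labels <- colnames(tab)
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = sep,
                             check.names = FALSE,
                             colClasses = c("character"))
    labels <- tab[[1]]
    values <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(values) <- "double")
  }
  if (anyNA(values)) {
    stop("malformed input: non-numeric or missing cells in ", path,
         call. = FALSE)
  }
  roi_timeseries(values, labels, tr_seconds, scan_id)
}

#' Write a region time series in the format [read_roi_timeseries()] reads
#'
#' @param ts a `roi_ts`.
#' @param path output file path.
#' @param orientation layout to write (see [read_roi_timeseries()]).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path,
                                 orientation = c("roi_rows", "roi_cols"),
                                 sep = ",") {
  orientation <- match.arg(orientation)
  if (orientation == "roi_cols") {
    tab <- as.data.frame(t(ts$values))
    colnames(tab) <- ts$roi_labels
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    tab <- data.frame(roi = ts$roi_labels, ts$values,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write / read the long-format connectivity table
#'
#' Long format: one row per scan, directed pair and window, columns
#' `scan_id, sender, receiver, window_index, window_start_s, capacity,
#' pcorr, swc, duration_trs`. The round trip through these two functions is
#' lossless (values printed at full precision).
#'
#' @param long data.frame from [connectivity_pairs()].
#' @param path output CSV path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_connectivity_long <- function(long, path) {
  fmt <- long
  for (col in c("capacity", "pcorr", "swc", "window_start_s")) {
    fmt[[col]] <- sprintf("%.17g", long[[col]])
    fmt[[col]][is.na(long[[col]])] <- "NA"
  }
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_long
#' @export
read_connectivity_long <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  for (col in c("capacity", "pcorr", "swc", "window_start_s")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab$window_index <- as.integer(tab$window_index)
  tab$duration_trs <- as.integer(tab$duration_trs)
  tab
}

#' Write a time-averaged connectivity matrix as labelled square CSV
#'
#' @param mat square matrix with region dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(mat, path, quote = FALSE)
  invisible(path)
}

#' Analysis configuration for the end-to-end pipeline
#'
#' Collects the meta-parameters of the sliding-window capacity analysis.
#' Window length may be given in seconds (converted per scan via TR) or in
#' samples.
#'
#' @param window value of the window length, in units of `window_unit`.
#' @param window_unit `"seconds"` or `"samples"`.
#' @param step_samples window step in samples.
#' @param criterion information criterion for order selection.
#' @param k_max maximum candidate order (`NULL` = per-window default).
#' @param grid_size DFT length for the capacity estimator.
#' @param log_base capacity unit, `"bits"` or `"nats"`.
#' @param cv_threshold,q_threshold,alpha statistical thresholds.
#' @param k_range,n_init,cluster_seed state-clustering settings.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(window = 50, window_unit = c("seconds", "samples"),
                            step_samples = 1,
                            criterion = c("BIC", "AIC", "AICc"),
                            k_max = NULL, grid_size = 4096,
                            log_base = c("bits", "nats"),
                            cv_threshold = 0.30, q_threshold = 0.02,
                            alpha = 0.02, k_range = 1:10, n_init = 6,
                            cluster_seed = 1) {
  window_unit <- match.arg(window_unit)
  criterion <- match.arg(criterion)
  log_base <- match.arg(log_base)
  stopifnot(window > 0, step_samples >= 1, grid_size >= 2)
  structure(
    list(window = window, window_unit = window_unit,
         step_samples = as.integer(step_samples), criterion = criterion,
         k_max = k_max, grid_size = as.integer(grid_size),
         log_base = log_base, cv_threshold = cv_threshold,
         q_threshold = q_threshold, alpha = alpha, k_range = k_range,
         n_init = n_init, cluster_seed = cluster_seed),
    class = "analysis_config"
  )
}

#' Run the sliding-window connectivity pipeline on a set of scans
#'
#' For every scan: plans windows from the configured length and step, runs
#' [connectivity_pairs()], and (optionally) writes the long-format table,
#' the per-scan time-averaged capacity matrices, and the resolved
#' configuration to `output_dir`.
#'
#' @param scans a `roi_ts` or list of them.
#' @param config an [analysis_config()].
#' @param output_dir directory for result files (`NULL` = return only).
#' @return list with `long` (stacked long table over scans) and
#'   `matrices` (named list of per-scan time-averaged capacity matrices).
#' @export
run_connectivity <- function(scans, config = analysis_config(),
                             output_dir = NULL) {
  if (inherits(scans, "roi_ts")) scans <- list(scans)
  longs <- list()
  mats <- list()
  for (ts in scans) {
    n <- if (config$window_unit == "seconds") {
      window_samples_from_seconds(config$window, ts$tr_seconds)
    } else {
      as.integer(config$window)
    }
    plan <- plan_windows(ncol(ts$values), n, config$step_samples)
    long <- connectivity_pairs(
      ts, plan = plan,
      config = order_config(config$criterion, config$k_max),
      grid_size = config$grid_size, log_base = config$log_base
    )
    longs[[ts$scan_id]] <- long
    mats[[ts$scan_id]] <- time_average_matrix(long, "capacity")
  }
  long_all <- do.call(rbind, longs)
  rownames(long_all) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_connectivity_long(long_all,
                            file.path(output_dir, "connectivity_long.csv"))
    for (id in names(mats)) {
      write_matrix_csv(mats[[id]],
                       file.path(output_dir,
                                 paste0("capacity_matrix_", id, ".csv")))
    }
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(output_dir, "config_resolved.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(long = long_all, matrices = mats)
}
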