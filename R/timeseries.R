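#' Region-by-volume BOLD time-series matrices
#'
#' A `dynfc_ts` object holds one participant-timepoint block of parcellated
#' BOLD signal: a numeric matrix with one row per region and one column per
#' volume, the repetition time in seconds, and the ordered region ids
#' matching the rows. Signal units are arbitrary; all downstream statistics
#' (Pearson correlation, coefficient of variation of correlations) are
#' invariant to per-region affine rescaling.
#'
#' @param data Numeric matrix, regions x volumes. Row names are taken as
#'   region names.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param region_ids Integer ids matching the rows; defaults to `1:nrow`.
#' @return A `dynfc_ts` object.
#' @export
timeseries_matrix <- function(data, tr_seconds, region_ids = seq_len(nrow(data))) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time series must be numeric", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("time series contains missing or non-finite values", call. = FALSE)
  }
  if (ncol(data) < 2) stop("time series must have at least 2 volumes", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number", call. = FALSE)
  }
  region_ids <- as.integer(region_ids)
  if (length(region_ids) != nrow(data)) {
    stop("region_ids length must match number of rows", call. = FALSE)
  }
  structure(list(data = data, tr_seconds = tr_seconds, region_ids = region_ids),
            class = "dynfc_ts")
}

#' @export
print.dynfc_ts <- function(x, ...) {
  cat(sprintf("<dynfc_ts> %d regions x %d volumes, TR = %g s (%.1f s scan)\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              ncol(x$data) * x$tr_seconds))
  invisible(x)
}

#' @export
dim.dynfc_ts <- function(x) dim(x$data)

#' Read and write region time series
#'
#' The on-disk format is a TSV with one header row of region names and one
#' data row per volume (the long time axis runs down the file). The reader
#' matches columns to the supplied region table by name, reorders them to
#' the table's order, and transposes to the internal regions-x-volumes
#' layout. The writer emits full double precision (`%.17g`) so that a
#' written file re-read through [read_timeseries()] reproduces the matrix
#' bit-identically.
#'
#' @param path File path.
#' @param region_table A validated region table whose `name` column defines
#'   the expected region columns and their order.
#' @param tr_seconds Repetition time in seconds attached to the result.
#' @return [read_timeseries()] returns a `dynfc_ts`; [write_timeseries()]
#'   returns the path invisibly.
#' @export
read_timeseries <- function(path, region_table, tr_seconds) {
  if (!file.exists(path)) stop("time series file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  missing <- setdiff(region_table$name, names(df))
  if (length(missing) > 0) {
    stop("time series file ", path, " is missing region column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, region_table$name, drop = FALSE]
  if (nrow(df) < 2) stop("time series must have at least 2 volumes", call. = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("non-numeric or missing value in time series file ", path, call. = FALSE)
  }
  out <- t(mat)                      # regions x volumes
  rownames(out) <- region_table$name
  colnames(out) <- NULL
  timeseries_matrix(out, tr_seconds, region_table$region_id)
}

#' @rdname read_timeseries
#' @param ts A `dynfc_ts` object.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "dynfc_ts"))
  mat <- t(ts$data)                  # volumes x regions on disk
  header <- paste(rownames(ts$data), collapse = "\t")
  body <- apply(mat, 1, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Scan timing arithmetic
#'
#' Converts volume counts to acquisition time given the repetition time
#' (TR). With the study configuration of 180 volumes at TR = 2.1 s the scan
#' lasts 378 s, i.e. 6 min 18 s.
#'
#' @param n_volumes Number of acquired volumes.
#' @param tr_seconds Repetition time in seconds.
#' @return Duration in seconds.
#' @export
scan_duration_seconds <- function(n_volumes, tr_seconds) {
  stopifnot(n_volumes >= 1, tr_seconds > 0)
  n_volumes * tr_seconds
}
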