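#' Sliding-window specification
#'
#' Defines the sliding window used for dynamic connectivity: a fixed length
#' in volumes advanced by a fixed step. The study configuration is a window
#' of 28 volumes (58.8 s at TR = 2.1 s) advanced by 5 volumes (10.5 s),
#' which yields 31 fully-contained windows in a 180-volume scan. Windows
#' are rectangular (no taper) and are truncated, never padded: only windows
#' lying fully inside the series count.
#'
#' @param length_volumes Window length L in volumes (>= 2).
#' @param step_volumes Step S in volumes (>= 1).
#' @return A `dynfc_window_spec` object.
#' @export
window_spec <- function(length_volumes = 28L, step_volumes = 5L) {
  length_volumes <- as.integer(length_volumes)
  step_volumes <- as.integer(step_volumes)
  if (is.na(length_volumes) || length_volumes < 2) {
    stop("window length must be an integer >= 2", call. = FALSE)
  }
  if (is.na(step_volumes) || step_volumes < 1) {
    stop("window step must be an integer >= 1", call. = FALSE)
  }
  structure(list(length_volumes = length_volumes, step_volumes = step_volumes),
            class = "dynfc_window_spec")
}

#' Enumerate sliding-window start indices
#'
#' Window starts are 1, 1+S, 1+2S, ...; every window `[start, start+L-1]`
#' must lie fully inside the series, so the count is
#' `floor((T - L)/S) + 1`. Volume indexing is 1-based.
#'
#' @param n_volumes Series length T in volumes.
#' @param spec A [window_spec()].
#' @return Integer vector of 1-based start indices.
#' @examples
#' length(enumerate_windows(180, window_spec(28, 5)))  # 31
#' @export
enumerate_windows <- function(n_volumes, spec) {
  stopifnot(inherits(spec, "dynfc_window_spec"))
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < spec$length_volumes) {
    stop("series shorter than window (", n_volumes, " < ",
         spec$length_volumes, " volumes)", call. = FALSE)
  }
  seq.int(1L, n_volumes - spec$length_volumes + 1L, by = spec$step_volumes)
}

#' Window timing in seconds
#'
#' @param spec A [window_spec()].
#' @param tr_seconds Repetition time in seconds.
#' @return Named numeric vector with elements `length_seconds` and
#'   `step_seconds`.
#' @export
window_duration_seconds <- function(spec, tr_seconds) {
  stopifnot(inherits(spec, "dynfc_window_spec"), tr_seconds > 0)
  c(length_seconds = spec$length_volumes * tr_seconds,
    step_seconds = spec$step_volumes * tr_seconds)
}

#' Windowed absolute Pearson correlation stack
#'
#' For each sliding window, computes the Pearson correlation matrix of the
#' windowed region signals and takes elementwise absolute values, so every
#' entry lies in \[0, 1\] and the sign of a coupling does not contribute to
#' its variability. Each matrix is symmetric with unit diagonal.
#'
#' @param ts A `dynfc_ts` time-series object.
#' @param spec A [window_spec()].
#' @return A `dynfc_window_stack`: a list with elements `windows` (list of
#'   W symmetric N x N matrices) and `window_starts` (1-based first-volume
#'   indices).
#' @export
windowed_abs_correlation <- function(ts, spec) {
  stopifnot(inherits(ts, "dynfc_ts"))
  starts <- enumerate_windows(ncol(ts$data), spec)
  L <- spec$length_volumes
  windows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    block <- ts$data[, starts[w]:(starts[w] + L - 1L), drop = FALSE]
    sds <- apply(block, 1, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      stop("region ", rownames(ts$data)[bad] %||% bad,
           " has zero variance in window ", w,
           " (volumes ", starts[w], "-", starts[w] + L - 1L, ")",
           call. = FALSE)
    }
    windows[[w]] <- abs(stats::cor(t(block)))
  }
  structure(list(windows = windows, window_starts = starts),
            class = "dynfc_window_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient-of-variation dFC matrix
#'
#' Per connection (unordered region pair), the dynamic functional
#' connectivity statistic is the coefficient of variation of the windowed
#' absolute correlations: the sample standard deviation (denominator
#' W - 1) over windows divided by the mean over windows. The statistic is
#' dimensionless and invariant to positive rescaling of a connection's
#' window series. Connections whose mean absolute correlation falls below
#' `mean_floor` are masked `NA` rather than divided out, to avoid exploding
#' ratios on near-zero couplings; the diagonal is always `NA`.
#'
#' @param stack A `dynfc_window_stack` with W >= 2 windows.
#' @param mean_floor Minimum mean window correlation for a finite CoV
#'   (default `1e-6`).
#' @return Symmetric N x N numeric matrix of CoV values with `NA` diagonal.
#' @export
cov_dfc <- function(stack, mean_floor = 1e-6) {
  stopifnot(inherits(stack, "dynfc_window_stack"))
  W <- length(stack$windows)
  if (W < 2) stop("need at least 2 windows to compute a standard deviation",
                  call. = FALSE)
  n <- nrow(stack$windows[[1]])
  flat <- vapply(stack$windows, as.vector, numeric(n * n))  # (N*N) x W
  mu_v <- rowMeans(flat)
  sd_v <- sqrt(rowSums((flat - mu_v)^2) / (W - 1))
  mu <- matrix(mu_v, n, n)
  out <- matrix(sd_v / mu_v, n, n)
  out[mu < mean_floor] <- NA_real_
  diag(out) <- NA_real_
  out
}

#' Network-level dFC summary
#'
#' Averages the dFC values of all connections between member regions of a
#' network and the rest of the parcellation (within-network pairs
#' excluded): with m members among N regions exactly m(N - m) connections
#' enter the unweighted mean. Masked (non-finite) connections are excluded.
#'
#' @param dfc A CoV matrix from [cov_dfc()], ordered as `regions`.
#' @param regions A region table matching the matrix rows.
#' @param network `"DMN"` or `"FPN"`.
#' @return Scalar network dFC.
#' @export
network_dfc <- function(dfc, regions, network = c("DMN", "FPN")) {
  network <- match.arg(network)
  if (nrow(dfc) != nrow(regions)) {
    stop("dFC matrix and region table disagree on region count", call. = FALSE)
  }
  members <- which(regions$network == network)
  if (length(members) == 0) stop("network ", network, " has no members",
                                 call. = FALSE)
  rest <- setdiff(seq_len(nrow(dfc)), members)
  vals <- as.vector(dfc[members, rest])
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop("all ", network, "-to-rest connections are masked", call. = FALSE)
  }
  mean(vals)
}

#' Whole-brain dFC summary
#'
#' Unweighted mean over all N(N-1)/2 unique off-diagonal connections of
#' the CoV matrix; masked connections are excluded.
#'
#' @param dfc A CoV matrix from [cov_dfc()].
#' @return Scalar whole-brain dFC.
#' @export
whole_brain_dfc <- function(dfc) {
  vals <- dfc[upper.tri(dfc)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("all connections are masked", call. = FALSE)
  mean(vals)
}

#' All network and whole-brain dFC summaries for one time series
#'
#' Convenience wrapper running the full per-scan pipeline: windowed
#' absolute correlations, CoV matrix, then DMN, FPN and whole-brain
#' averages.
#'
#' @inheritParams windowed_abs_correlation
#' @inheritParams cov_dfc
#' @param regions Region table matching the series rows.
#' @return Named numeric vector `c(DMN_dFC, FPN_dFC, WB_dFC)`.
#' @export
dfc_summaries <- function(ts, regions, spec = window_spec(),
                          mean_floor = 1e-6) {
  stack <- windowed_abs_correlation(ts, spec)
  dfc <- cov_dfc(stack, mean_floor)
  c(DMN_dFC = network_dfc(dfc, regions, "DMN"),
    FPN_dFC = network_dfc(dfc, regions, "FPN"),
    WB_dFC = whole_brain_dfc(dfc))
}
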