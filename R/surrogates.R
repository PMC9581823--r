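#' Multivariate phase-randomization surrogate
#'
#' Builds a surrogate time series by rotating the phases of the discrete
#' Fourier transform and inverting: one random phase offset, uniform on
#' \[0, 2\*pi) per positive frequency, is drawn and applied *identically to
#' every region's spectrum*, with conjugate-symmetric phases on negative
#' frequencies; the DC bin (and the Nyquist bin for even-length series) is
#' left untouched so the output stays real. Because all regions share one
#' phase vector, every cross-spectrum — and hence every full-length
#' pairwise Pearson correlation and every autocorrelation function — is
#' preserved to numerical precision, while genuine time-localized coupling
#' dynamics are destroyed. This is the multivariate surrogate construction
#' of the Fourier-transform (phase-randomization) family.
#'
#' @param ts A `dynfc_ts` with at least 4 volumes.
#' @param seed Integer seed for the phase draw.
#' @param phases Optional numeric vector of phase offsets (one per positive
#'   non-Nyquist frequency, `floor((T-1)/2)` values) overriding the random
#'   draw; `phases = 0` (recycled) reproduces the input exactly and serves
#'   as an identity test hook.
#' @return A `dynfc_ts` surrogate of identical shape.
#' @export
phase_randomize <- function(ts, seed = NULL, phases = NULL) {
  stopifnot(inherits(ts, "dynfc_ts"))
  x <- ts$data
  n <- ncol(x)
  if (n < 4) stop("need at least 4 volumes for phase randomization", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  npos <- (n - 1L) %/% 2L           # positive non-Nyquist frequencies
  if (is.null(phases)) {
    if (is.null(seed)) stop("either seed or phases must be supplied", call. = FALSE)
    set.seed(as.integer(seed))
    phases <- stats::runif(npos, 0, 2 * pi)
  } else {
    phases <- rep_len(as.numeric(phases), npos)
  }
  rot <- complex(modulus = 1, argument = numeric(n))
  rot[1L + seq_len(npos)] <- complex(modulus = 1, argument = phases)
  rot[n + 1L - seq_len(npos)] <- Conj(rot[1L + seq_len(npos)])
  # rot[1] (DC) and, for even n, rot[n/2 + 1] (Nyquist) stay at 1
  spectra <- stats::mvfft(t(x))     # frequencies x regions
  rotated <- spectra * rot          # common phase vector, recycled by column
  surrogate <- Re(stats::mvfft(rotated, inverse = TRUE)) / n
  out <- t(surrogate)
  dimnames(out) <- dimnames(x)
  timeseries_matrix(out, ts$tr_seconds, ts$region_ids)
}

#' Surrogate ensemble
#'
#' Generates K independent phase-randomized copies. Sub-seeds are derived
#' from the master seed by a counter scheme (`seed + k` for copy k), so
#' regeneration from the same `(seed, K, input)` is bit-identical and
#' copies can be generated independently.
#'
#' @inheritParams phase_randomize
#' @param K Ensemble size (>= 1); the study configuration uses 20 copies.
#' @return List of K `dynfc_ts` surrogates.
#' @export
surrogate_ensemble <- function(ts, K = 20L, seed = 1L) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  lapply(seq_len(K), function(k) phase_randomize(ts, seed = seed + k))
}

#' Surrogate whole-brain dFC
#'
#' Mean whole-brain dFC over an ensemble of K phase-randomized surrogates
#' of one scan; the null value against which observed whole-brain dFC is
#' compared.
#'
#' @inheritParams surrogate_ensemble
#' @param spec A [window_spec()].
#' @param mean_floor Passed to [cov_dfc()].
#' @return Scalar: ensemble mean of the surrogate whole-brain dFC.
#' @export
surrogate_whole_brain_dfc <- function(ts, spec = window_spec(), K = 20L,
                                      seed = 1L, mean_floor = 1e-6) {
  copies <- surrogate_ensemble(ts, K = K, seed = seed)
  vals <- vapply(copies, function(s) {
    whole_brain_dfc(cov_dfc(windowed_abs_correlation(s, spec), mean_floor))
  }, numeric(1))
  mean(vals)
}

#' Paired test of observed versus surrogate dFC
#'
#' Two-sided paired Student t-test of per-participant observed whole-brain
#' dFC against the matched surrogate-ensemble means, with df = n - 1. A
#' significant positive statistic indicates that observed connectivity
#' variability exceeds what stationary correlation plus autocorrelation
#' alone produce, i.e. that it reflects genuine dynamics rather than
#' sampling noise. If all pairwise differences are exactly zero the test
#' degenerates to t = 0, p = 1; zero-variance differences with a nonzero
#' mean are an error.
#'
#' @param observed Numeric vector of observed whole-brain dFC, one per
#'   participant.
#' @param surrogate_means Matched numeric vector of surrogate-ensemble
#'   means.
#' @return List with elements `t`, `df`, `p`.
#' @export
surrogate_paired_test <- function(observed, surrogate_means) {
  if (length(observed) != length(surrogate_means)) {
    stop("observed and surrogate vectors differ in length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  d <- observed - surrogate_means
  if (anyNA(d)) stop("missing values in paired dFC", call. = FALSE)
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (max(abs(d)) <= 1e-12 * max(abs(observed), 1)) {
      return(list(t = 0, df = n - 1L, p = 1))
    }
    stop("zero variance of nonzero differences: paired t undefined",
         call. = FALSE)
  }
  fit <- stats::t.test(observed, surrogate_means, paired = TRUE)
  list(t = unname(fit$statistic), df = as.integer(unname(fit$parameter)),
       p = fit$p.value)
}
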