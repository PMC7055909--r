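#' Estimate the fundamental frequency of a voiced segment
#'
#' Autocorrelation method: the biased autocorrelation is computed by FFT,
#' normalized by lag zero, and its highest peak over the candidate lag
#' range `[1/fmax, 1/fmin]` is refined by parabolic interpolation.  A
#' normalized peak below `voicing_threshold` raises an "unvoiced" error.
#'
#' @param seg An [utterance_segment()] or [waveform_record()].
#' @param fmin_hz,fmax_hz Search band in Hz.
#' @param voicing_threshold Minimum normalized autocorrelation peak.
#' @return Estimated f0 in Hz.
#' @examples
#' rec <- synthesize_waveform(voice_profile("modal", f0_hz = 220),
#'                            duration_s = 1, rate_hz = 8000,
#'                            silence_s = 0, seed = 3)
#' estimate_f0(rec)
#' @export
estimate_f0 <- function(seg, fmin_hz = 100, fmax_hz = 400,
                        voicing_threshold = 0.3) {
  if (fmin_hz >= fmax_hz) stop("need fmin_hz < fmax_hz", call. = FALSE)
  x <- .segment_samples(seg)
  rate <- .segment_rate(seg)
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(n)] / nfft
  if (r[1] <= 0) stop("unvoiced segment (no signal energy)", call. = FALSE)
  r <- r / r[1]

  lag_min <- max(2L, floor(rate / fmax_hz))
  lag_max <- min(n - 2L, ceiling(rate / fmin_hz))
  if (lag_min >= lag_max)
    stop("f0 search band not resolvable at this rate/segment length",
         call. = FALSE)
  lags <- lag_min:lag_max
  k <- lags[which.max(r[lags + 1L])]
  if (r[k + 1L] < voicing_threshold)
    stop("unvoiced segment (autocorrelation peak ",
         signif(r[k + 1L], 3), " < ", voicing_threshold, ")", call. = FALSE)
  # parabolic refinement around the integer-lag peak
  y1 <- r[k]; y2 <- r[k + 1L]; y3 <- r[k + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  rate / (k + delta)
}

#' Detect vocal cycles by peak picking
#'
#' Locates one maximal positive peak per pitch period: starting from the
#' highest sample in the first 1.5 periods, each next peak is searched in a
#' window `[0.5, 1.5] / f0` after the previous one.  Peak positions and
#' magnitudes are refined by parabolic interpolation, giving sub-sample
#' period estimates.  Cycles whose period falls outside `[0.5, 2] / f0`
#' are discarded.
#'
#' @param seg An [utterance_segment()] or [waveform_record()].
#' @param f0_hz Fundamental frequency in Hz (see [estimate_f0()]).
#' @return A `cycle_series`: list with `periods_s` (inter-peak intervals,
#'   seconds), `peak_amps` (refined peak magnitudes, one per cycle),
#'   `peak_times_s`, and `n_cycles`.
#' @export
detect_cycles <- function(seg, f0_hz) {
  stopifnot(f0_hz > 0)
  x <- .segment_samples(seg)
  rate <- .segment_rate(seg)
  period <- rate / f0_hz
  n <- length(x)
  if (n < 2.5 * period)
    stop("insufficient cycles: segment shorter than two pitch periods",
         call. = FALSE)
  if (max(x) <= 0)
    stop("insufficient cycles: no positive peaks in segment", call. = FALSE)

  first_end <- min(n, ceiling(1.5 * period))
  p <- which.max(x[seq_len(first_end)])
  peaks <- p
  repeat {
    lo <- round(p + 0.5 * period)
    hi <- round(p + 1.5 * period)
    if (hi > n) break
    p <- lo - 1L + which.max(x[lo:hi])
    peaks <- c(peaks, p)
  }
  if (length(peaks) < 3L)
    stop("insufficient cycles detected", call. = FALSE)

  ref <- vapply(peaks, function(k) {
    if (k <= 1L || k >= n) return(c(k, x[k]))
    y1 <- x[k - 1L]; y2 <- x[k]; y3 <- x[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom == 0) return(c(k, x[k]))
    d <- 0.5 * (y1 - y3) / denom
    c(k + d, y2 - 0.25 * (y1 - y3) * d)
  }, c(0, 0))
  pos <- ref[1, ]; amp <- ref[2, ]

  periods <- diff(pos) / rate
  keep <- periods >= 0.5 / f0_hz & periods <= 2 / f0_hz
  periods <- periods[keep]
  amp <- amp[-1][keep]          # amplitude of the cycle ending at each peak
  times <- pos[-1][keep] / rate
  if (length(periods) < 2L)
    stop("insufficient cycles after period gating", call. = FALSE)
  structure(
    list(periods_s = periods, peak_amps = amp, peak_times_s = times,
         n_cycles = length(periods)),
    class = "cycle_series")
}

#' Construct a cycle series from known periods and amplitudes
#'
#' @param periods_s Per-cycle periods in seconds (all positive).
#' @param peak_amps Per-cycle peak magnitudes.
#' @return A `cycle_series`.
#' @export
cycle_series <- function(periods_s, peak_amps) {
  periods_s <- as.numeric(periods_s); peak_amps <- as.numeric(peak_amps)
  if (length(periods_s) != length(peak_amps))
    stop("periods and amplitudes must have equal length", call. = FALSE)
  if (length(periods_s) < 2L)
    stop("need at least 2 cycles for perturbation measures", call. = FALSE)
  if (any(periods_s <= 0)) stop("all periods must be positive", call. = FALSE)
  structure(list(periods_s = periods_s, peak_amps = peak_amps,
                 peak_times_s = cumsum(periods_s),
                 n_cycles = length(periods_s)),
            class = "cycle_series")
}

#' Relative jitter
#'
#' Mean absolute difference between consecutive cycle periods, relative to
#' the mean period:
#' `Jr = mean(|T_i - T_{i+1}|) / mean(T_i)`.
#' Dimensionless fraction (multiply by 100 for percent); invariant under
#' uniform time dilation.
#'
#' @param cycles A `cycle_series`.
#' @return Relative jitter as a fraction.
#' @examples
#' jitter_rel(cycle_series(c(0.010, 0.011, 0.010, 0.011), rep(1, 4)))
#' @export
jitter_rel <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_series"))
  per <- cycles$periods_s
  mean(abs(diff(per))) / mean(per)
}

#' Relative shimmer
#'
#' Mean absolute difference between consecutive cycle peak amplitudes,
#' relative to the mean amplitude:
#' `Sr = mean(|A_i - A_{i+1}|) / mean(A_i)`.
#' Dimensionless fraction; invariant under uniform gain.
#'
#' @param cycles A `cycle_series`.
#' @return Relative shimmer as a fraction.
#' @examples
#' shimmer_rel(cycle_series(rep(0.005, 4), c(1, 1.2, 1, 1.2)))
#' @export
shimmer_rel <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_series"))
  A <- cycles$peak_amps
  m <- mean(A)
  if (m == 0) stop("zero mean amplitude; shimmer undefined", call. = FALSE)
  mean(abs(diff(A))) / m
}
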