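#' Synthesize a neck-surface-vibration-like waveform
#'
#' Generates a quasi-periodic additive-harmonic signal, cycle by cycle.
#' Cycle k has period `T_k = (1/f0) * (1 + e_k)` and amplitude
#' `A_k = 1 + d_k`, where `e_k` and `d_k` are i.i.d. Gaussian deviates
#' rescaled so that the realized relative jitter and shimmer, evaluated on
#' the stored truth cycles with the same formulas used by
#' [jitter_rel()]/[shimmer_rel()], equal the profile's targets exactly.
#' Broadband Gaussian noise, band-limited to the ~3 kHz pass band of a
#' neck-surface accelerometer, is added over the voiced portion at the
#' profile's SNR, and `silence_s` seconds of near-silence (dither 80 dB
#' below the signal peak, so the zero-crossing rate is defined) are
#' prepended and appended.  The assembled record is scaled to a peak
#' amplitude of 0.9 (recorder headroom); every extracted feature is
#' invariant to this gain.
#'
#' @param profile A [voice_profile()].
#' @param duration_s Target voiced duration in seconds (>= 0.5).  The
#'   realized voiced duration is the nearest whole number of cycles.
#' @param rate_hz Sampling rate in Hz.  Must be at least 4 times the highest
#'   synthesized harmonic (`20 * f0`).
#' @param silence_s Seconds of near-silence added before and after the
#'   voiced portion.
#' @param seed Integer seed; every random draw is governed by it.
#' @param random_phase If `TRUE` harmonic phases are drawn uniformly;
#'   default is an all-cosine stack (phase does not affect any extracted
#'   feature).
#' @return A `waveform_record`: list with `samples`, `rate_hz`,
#'   `duration_s` and a `truth` list holding the profile, realized `f0_hz`,
#'   exact cycle start times/indices, per-cycle periods and amplitudes, and
#'   the silence extents.
#' @examples
#' rec <- synthesize_waveform(voice_profile("breathy", f0_hz = 220),
#'                            duration_s = 1, rate_hz = 8000, seed = 1)
#' rec
#' @export
synthesize_waveform <- function(profile, duration_s = 2, rate_hz = 44100,
                                silence_s = 0.5, seed = NULL,
                                random_phase = FALSE) {
  stopifnot(inherits(profile, "voice_profile"))
  if (duration_s < 0.5) stop("duration_s must be >= 0.5 s", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  if (silence_s < 0) stop("silence_s must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  f0 <- profile$f0_hz
  if (is.null(f0)) f0 <- stats::runif(1, 180, 250)
  if (f0 >= rate_hz / 10)
    stop("f0 too high for this sampling rate (harmonics would alias): ",
         "need rate_hz >= 20 * f0", call. = FALSE)

  n_cycles <- max(3L, round(duration_s * f0))
  T0 <- 1 / f0

  periods <- T0 * (1 + .calibrated_deviates(n_cycles, profile$jitter_pct / 100))
  amps    <-  1 * (1 + .calibrated_deviates(n_cycles, profile$shimmer_pct / 100))

  starts <- c(0, cumsum(periods))           # cycle start times, seconds
  voiced_dur <- starts[n_cycles + 1L]
  n_voiced <- floor(voiced_dur * rate_hz)
  t <- (seq_len(n_voiced) - 1L) / rate_hz
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx > n_cycles] <- n_cycles
  phase <- (t - starts[idx]) / periods[idx]

  w <- profile$harmonic_weights
  theta <- if (random_phase) stats::runif(5, 0, 2 * pi) else rep(0, 5)
  s <- numeric(n_voiced)
  for (i in 1:5)
    if (w[i] > 0) s <- s + w[i] * cos(2 * pi * i * phase + theta[i])
  # raised-cosine amplitude envelope between consecutive cycle-start peaks:
  # stationary at each peak, so the waveform maximum of cycle k sits exactly
  # at the cycle start with amplitude amps[k], and the signal is continuous
  amps_next <- c(amps[-1L], amps[n_cycles])
  env <- amps[idx] + (amps_next[idx] - amps[idx]) * (1 - cos(pi * phase)) / 2
  s <- s * env

  if (is.finite(profile$noise_snr_db)) {
    # noise is band-limited to the sensor band (the neck-surface
    # accelerometer passes little above ~3 kHz), so the broadband floor
    # lands inside the spectral-entropy band regardless of sampling rate
    p_sig <- mean(s^2)
    noise_sd <- sqrt(p_sig / 10^(profile$noise_snr_db / 10))
    noise <- .bandlimit(stats::rnorm(n_voiced), rate_hz, 3000)
    s <- s + noise * noise_sd / sqrt(mean(noise^2))
  } else {
    noise_sd <- 0
  }

  n_sil <- round(silence_s * rate_hz)
  dither_sd <- max(abs(s)) * 10^(-80 / 20)
  pre  <- stats::rnorm(n_sil, sd = dither_sd)
  post <- stats::rnorm(n_sil, sd = dither_sd)
  samples <- c(pre, s, post)
  samples <- samples * (0.9 / max(abs(samples)))   # recorder headroom

  truth <- list(
    profile = profile,
    f0_hz = f0,
    cycle_start_s = starts,                         # length n_cycles + 1
    cycle_start_idx = n_sil + 1L + floor(starts * rate_hz),  # 1-based
    periods_s = periods,
    amplitudes = amps,
    silence_s = n_sil / rate_hz,
    voiced_range_idx = c(n_sil + 1L, n_sil + n_voiced),
    noise_sd = noise_sd)

  waveform_record(samples, rate_hz, truth = truth)
}

# Brick-wall FFT low-pass; identity when the cutoff is at/above Nyquist.
.bandlimit <- function(x, rate_hz, cutoff_hz) {
  n <- length(x)
  if (cutoff_hz >= rate_hz / 2) return(x)
  f <- (seq_len(n) - 1L) / n * rate_hz
  f <- pmin(f, rate_hz - f)             # two-sided bin frequencies
  X <- stats::fft(x)
  X[f > cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Draw n i.i.d. Gaussian deviates and rescale them so that the realized
# relative perturbation mean(|x[i]-x[i+1]|)/mean(x) of x = 1 + a*e equals
# `target` exactly: a = J / (A - J*m) with A = mean|diff(e)|, m = mean(e).
.calibrated_deviates <- function(n, target) {
  if (target == 0) return(numeric(n))
  e <- stats::rnorm(n)
  A <- mean(abs(diff(e)))
  m <- mean(e)
  a <- target / (A - target * m)
  a * e
}

#' Construct a waveform record
#'
#' The raw input unit of the pipeline: a sampled real-valued vibration
#' signal plus its sampling rate, with optional ground truth attached by
#' the generator.
#'
#' @param samples Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz.
#' @param truth Optional list of generation ground truth.
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(samples, rate_hz, truth = NULL) {
  samples <- as.numeric(samples)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  if (!is.null(truth) && !is.null(truth$cycle_start_idx)) {
    ci <- truth$cycle_start_idx
    if (is.unsorted(ci, strictly = TRUE) ||
        ci[1] < 1L || ci[length(ci)] > length(samples) + 1L)
      stop("truth cycle boundaries must be strictly increasing and inside the signal",
           call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = rate_hz,
         duration_s = length(samples) / rate_hz, truth = truth),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("Waveform record: %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate_hz, x$duration_s))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %s, f0 = %.1f Hz, %d cycles, silence %.2f s/side\n",
                x$truth$profile$name, x$truth$f0_hz,
                length(x$truth$periods_s), x$truth$silence_s))
  }
  invisible(x)
}
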