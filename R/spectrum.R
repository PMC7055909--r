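#' Magnitude spectrum of an utterance
#'
#' Computes one whole-utterance magnitude spectrum: the segment is
#' amplitude-normalized to unit peak, Hamming-windowed, and zero-padded to
#' the next power of two giving a bin spacing of at most `resolution_hz`.
#' Magnitudes are normalized to a maximum of 1, removing loudness from the
#' spectral features.
#'
#' @param seg An [utterance_segment()] (or a [waveform_record()], taken
#'   whole).
#' @param resolution_hz Maximum bin spacing in Hz (default 1 Hz, matching
#'   harmonic-analysis practice for sustained vowels).
#' @return A `spectrum_view`: list with `freqs_hz`, `magnitude` (max 1) and
#'   `resolution_hz`.
#' @examples
#' seg <- waveform_record(sin(2 * pi * 200 * (0:15999) / 8000), 8000)
#' sp <- compute_spectrum(seg)
#' sp$freqs_hz[which.max(sp$magnitude)]
#' @export
compute_spectrum <- function(seg, resolution_hz = 1) {
  x <- .segment_samples(seg)
  rate <- .segment_rate(seg)
  if (length(x) == 0) stop("empty segment", call. = FALSE)
  if (length(x) / rate < 0.5)
    stop("segment shorter than 0.5 s", call. = FALSE)
  peak <- max(abs(x))
  if (peak == 0) stop("all-zero segment", call. = FALSE)
  x <- x / peak

  n <- length(x)
  w <- .hamming(n)
  # pad to >= 4x the data length as well as the resolution target: the
  # fine interpolation keeps off-bin peak magnitudes within ~1% of their
  # true windowed value (negligible scalloping loss)
  nfft <- 2^ceiling(log2(max(4 * n, rate / resolution_hz)))
  X <- stats::fft(c(x * w, numeric(nfft - n)))
  half <- nfft %/% 2 + 1L
  mag <- Mod(X[seq_len(half)])
  mag <- mag / max(mag)
  structure(
    list(freqs_hz = (seq_len(half) - 1) * rate / nfft,
         magnitude = mag,
         resolution_hz = rate / nfft),
    class = "spectrum_view")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

.segment_samples <- function(seg) {
  if (inherits(seg, "utterance_segment") || inherits(seg, "waveform_record"))
    seg$samples
  else as.numeric(seg)
}

.segment_rate <- function(seg) {
  if (inherits(seg, "utterance_segment") || inherits(seg, "waveform_record"))
    seg$rate_hz
  else stop("need an utterance_segment or waveform_record", call. = FALSE)
}

#' Harmonic spectral quotients H1..H4
#'
#' The amplitude `A_i` of the i-th harmonic (i = 1..5) is the maximum
#' spectral magnitude within `f0/4` of `i * f0`, restricted to the
#' 50-1500 Hz analysis band; harmonics whose predicted location exceeds
#' `band_hz[2]` contribute `A_i = 0`.  The quotients are
#' `H_i = A_i / (A_1 + ... + A_5)`, so the five of them sum to one; the
#' first four are returned (H5 is linearly redundant).
#'
#' @param spec A `spectrum_view` from [compute_spectrum()].
#' @param f0_hz Fundamental frequency in Hz.
#' @param band_hz Analysis band, default `c(50, 1500)`.
#' @param n_harmonics Number of harmonics in the normalising sum (5).
#' @return Named numeric vector `c(H1, H2, H3, H4)`; the full amplitude
#'   vector is attached as attribute `"amplitudes"`.
#' @export
harmonic_quotients <- function(spec, f0_hz, band_hz = c(50, 1500),
                               n_harmonics = 5L) {
  stopifnot(inherits(spec, "spectrum_view"), f0_hz > 0)
  A <- vapply(seq_len(n_harmonics), function(i) {
    target <- i * f0_hz
    if (target > band_hz[2]) return(0)
    lo <- max(target - f0_hz / 4, band_hz[1])
    hi <- min(target + f0_hz / 4, band_hz[2])
    sel <- which(spec$freqs_hz >= lo & spec$freqs_hz <= hi)
    if (!length(sel)) return(0)
    k <- sel[which.max(spec$magnitude[sel])]
    # parabolic refinement of the peak magnitude removes the residual
    # scalloping loss of the discrete bins
    if (k > 1L && k < length(spec$magnitude)) {
      y1 <- spec$magnitude[k - 1L]; y2 <- spec$magnitude[k]
      y3 <- spec$magnitude[k + 1L]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) {
        d <- 0.5 * (y1 - y3) / denom
        return(y2 - 0.25 * (y1 - y3) * d)
      }
    }
    spec$magnitude[k]
  }, 0)
  s <- sum(A)
  if (s == 0) stop("all harmonic amplitudes are zero; quotients undefined",
                   call. = FALSE)
  H <- A / s
  out <- H[1:4]
  names(out) <- paste0("H", 1:4)
  attr(out, "amplitudes") <- A
  out
}

#' Spectral entropy
#'
#' Shannon entropy of the normalized spectral density over `band_hz`
#' (default 0-3000 Hz, the sensor's useful band): with
#' `p_i = |X_i|^2 / sum |X_j|^2`, `SE = -sum p_i log p_i` (0 log 0 := 0).
#' Small for tonal signals, large for noise-like signals; invariant under
#' uniform amplitude scaling.
#'
#' @param spec A `spectrum_view` from [compute_spectrum()].
#' @param band_hz Integration band in Hz, default `c(0, 3000)`.
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return Spectral entropy (nonnegative scalar, at most `log(n_bins)`).
#' @export
spectral_entropy <- function(spec, band_hz = c(0, 3000), base = exp(1)) {
  stopifnot(inherits(spec, "spectrum_view"))
  sel <- spec$freqs_hz >= band_hz[1] & spec$freqs_hz <= band_hz[2]
  d <- spec$magnitude[sel]^2
  tot <- sum(d)
  if (tot == 0) stop("no spectral energy in the entropy band", call. = FALSE)
  p <- d[d > 0] / tot
  -sum(p * log(p, base = base))
}
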