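#' Short-time energy and zero-crossing rate
#'
#' Frames the signal into `frame_s`-second windows advanced by `hop_s`
#' (trailing partial frame dropped) and computes, per frame, the mean
#' squared sample (energy) and the sign-change rate in crossings per
#' second.
#'
#' @param rec A [waveform_record()].
#' @param frame_s Frame length in seconds.
#' @param hop_s Hop (frame advance) in seconds.
#' @return A data frame with columns `frame` (1-based), `start_idx`
#'   (1-based first sample), `t_s` (frame start time), `energy`, `zcr`
#'   (crossings per second).
#' @examples
#' rec <- waveform_record(sin(2 * pi * 100 * (0:7999) / 8000), 8000)
#' head(short_time_features(rec))
#' @export
short_time_features <- function(rec, frame_s = 0.025, hop_s = 0.010) {
  stopifnot(inherits(rec, "waveform_record"))
  if (hop_s <= 0 || frame_s < hop_s)
    stop("need 0 < hop_s <= frame_s", call. = FALSE)
  n_frame <- round(frame_s * rec$rate_hz)
  n_hop <- round(hop_s * rec$rate_hz)
  n <- length(rec$samples)
  if (n_frame > n) stop("frame longer than the signal", call. = FALSE)
  starts <- seq(1L, n - n_frame + 1L, by = n_hop)
  x <- rec$samples
  energy <- vapply(starts, function(s) mean(x[s:(s + n_frame - 1L)]^2), 0)
  zcr <- vapply(starts, function(s) {
    seg <- x[s:(s + n_frame - 1L)]
    sum(abs(diff(sign(seg))) > 0) / frame_s
  }, 0)
  data.frame(frame = seq_along(starts), start_idx = starts,
             t_s = (starts - 1L) / rec$rate_hz, energy = energy, zcr = zcr)
}

#' Detect the voiced utterance in a recording
#'
#' Voice activity detection by short-time energy and zero-crossing rate: a
#' frame is voiced when its energy exceeds `energy_factor` times the noise
#' floor (median energy of the lowest-decile frames) and its zero-crossing
#' rate is below `zcr_ceiling`.  The frame-level voiced mask is smoothed by
#' a 3-frame majority filter (hangover smoothing) and the longest
#' contiguous voiced run is returned as an utterance segment (one
#' sustained vowel per recording is assumed).  For recordings with no silence at all the energy threshold is
#' capped at a tenth of the peak frame energy, so a fully voiced record is
#' returned whole.
#'
#' @param rec A [waveform_record()].
#' @param frame_s,hop_s Framing parameters, see [short_time_features()].
#' @param energy_factor Multiplier on the noise-floor energy.
#' @param zcr_ceiling Maximum voiced zero-crossing rate, crossings/s.
#' @param min_voiced_s Minimum acceptable voiced run, seconds.
#' @return An `utterance_segment`: list with 1-based `start_idx`,
#'   `end_idx` (inclusive), `start_s`, `end_s` and the parent record.
#' @examples
#' rec <- synthesize_waveform(voice_profile("modal", f0_hz = 200),
#'                            duration_s = 1, rate_hz = 8000,
#'                            silence_s = 0.3, seed = 2)
#' detect_utterance(rec)
#' @export
detect_utterance <- function(rec, frame_s = 0.025, hop_s = 0.010,
                             energy_factor = 10, zcr_ceiling = 3000,
                             min_voiced_s = 0.3) {
  stf <- short_time_features(rec, frame_s, hop_s)
  e <- stf$energy
  lowest <- sort(e)[seq_len(max(1L, ceiling(length(e) / 10)))]
  floor_e <- stats::median(lowest)
  thresh <- min(energy_factor * floor_e, 0.1 * max(e))
  voiced <- e > thresh & stf$zcr < zcr_ceiling
  # 3-frame majority smoothing (hangover): single-frame dropouts at the
  # zcr boundary must not fragment a sustained vowel
  if (length(voiced) >= 3) {
    n <- length(voiced)
    voiced <- (voiced + c(voiced[1], voiced[-n]) + c(voiced[-1], voiced[n])) >= 2
  }

  r <- rle(voiced)
  if (!any(r$values)) stop("no voiced region found", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  f1 <- starts[best]; f2 <- ends[best]

  n_frame <- round(frame_s * rec$rate_hz)
  i1 <- stf$start_idx[f1]
  i2 <- min(stf$start_idx[f2] + n_frame - 1L, length(rec$samples))
  if ((i2 - i1 + 1L) / rec$rate_hz < min_voiced_s)
    stop("no voiced region of at least ", min_voiced_s, " s found",
         call. = FALSE)
  utterance_segment(rec, i1, i2)
}

#' Construct an utterance segment
#'
#' @param rec Parent [waveform_record()].
#' @param start_idx,end_idx 1-based inclusive sample bounds.
#' @return An object of class `utterance_segment`.
#' @export
utterance_segment <- function(rec, start_idx, end_idx) {
  stopifnot(inherits(rec, "waveform_record"))
  if (start_idx < 1L || end_idx > length(rec$samples) || start_idx >= end_idx)
    stop("segment bounds must satisfy 1 <= start < end <= length(samples)",
         call. = FALSE)
  structure(
    list(start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
         start_s = (start_idx - 1L) / rec$rate_hz,
         end_s = end_idx / rec$rate_hz,
         rate_hz = rec$rate_hz,
         samples = rec$samples[start_idx:end_idx]),
    class = "utterance_segment")
}

#' @export
print.utterance_segment <- function(x, ...) {
  cat(sprintf("Utterance segment: samples %d..%d (%.3f-%.3f s, %.3f s) @ %g Hz\n",
              x$start_idx, x$end_idx, x$start_s, x$end_s,
              x$end_s - x$start_s, x$rate_hz))
  invisible(x)
}
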