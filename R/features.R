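#' Extract the seven-dimensional voice-type feature vector
#'
#' Runs the full per-recording chain: voice activity detection, one
#' whole-utterance Hamming spectrum, autocorrelation f0, harmonic quotients
#' H1-H4 over 50-1500 Hz, spectral entropy over 0-3000 Hz, and cycle-level
#' relative jitter and shimmer.  The result is the classification unit
#' `[H1, H2, H3, H4, SE, Jr, Sr]`.
#'
#' Stage failures are re-raised with the failing stage's name prefixed.
#'
#' @param rec A [waveform_record()].
#' @param vad_params List of arguments passed to [detect_utterance()]; set
#'   to `NULL` to skip VAD and use the whole record.
#' @param f0_range_hz f0 search band, default `c(100, 400)`.
#' @param harmonic_band_hz Harmonic analysis band, default `c(50, 1500)`.
#' @param entropy_band_hz Spectral-entropy band, default `c(0, 3000)`.
#' @param entropy_base Logarithm base for the entropy, default natural log.
#' @return A one-row data frame with columns `H1..H4`, `SE`, `Jr`, `Sr`,
#'   `f0_hz` and `label` (the truth profile name if present, else `NA`).
#' @examples
#' rec <- synthesize_waveform(voice_profile("modal", f0_hz = 210),
#'                            duration_s = 1, rate_hz = 8000, seed = 4)
#' extract_features(rec)
#' @export
extract_features <- function(rec,
                             vad_params = list(),
                             f0_range_hz = c(100, 400),
                             harmonic_band_hz = c(50, 1500),
                             entropy_band_hz = c(0, 3000),
                             entropy_base = exp(1)) {
  stopifnot(inherits(rec, "waveform_record"))
  seg <- if (is.null(vad_params)) rec else
    .stage("vad", do.call(detect_utterance, c(list(rec), vad_params)))
  spec <- .stage("spectrum", compute_spectrum(seg))
  f0 <- .stage("f0", estimate_f0(seg, f0_range_hz[1], f0_range_hz[2]))
  H <- .stage("harmonics", harmonic_quotients(spec, f0, harmonic_band_hz))
  SE <- .stage("entropy",
               spectral_entropy(spec, entropy_band_hz, entropy_base))
  cyc <- .stage("cycles", detect_cycles(seg, f0))
  Jr <- jitter_rel(cyc)
  Sr <- shimmer_rel(cyc)
  label <- if (!is.null(rec$truth)) rec$truth$profile$name else NA_character_
  data.frame(H1 = H[["H1"]], H2 = H[["H2"]], H3 = H[["H3"]], H4 = H[["H4"]],
             SE = SE, Jr = Jr, Sr = Sr, f0_hz = f0, label = label,
             stringsAsFactors = FALSE)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Extract features for a batch of records
#'
#' @param recs List of [waveform_record()] objects (or paths to WAV files).
#' @param ids Optional sample identifiers (default `sample_1 ...`).
#' @param ... Passed to [extract_features()].
#' @return Data frame with one row per record and a `sample_id` column.
#' @export
extract_features_batch <- function(recs, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_along(recs))
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.character(r)) r <- read_wav(r)
    cbind(data.frame(sample_id = ids[i], stringsAsFactors = FALSE),
          extract_features(r, ...))
  })
  do.call(rbind, rows)
}
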