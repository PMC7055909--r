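#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed integer PCM (8/16/24/32 bit)
#' and IEEE float (32 bit).  Samples are returned as doubles scaled to
#' [-1, 1].  Multi-channel files are reduced to the first channel with a
#' warning.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform_record()] (no truth attached).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")     # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = .le_uint(fmt_raw[1:2]),
        n_channels   = .le_uint(fmt_raw[3:4]),
        rate_hz      = .le_uint(fmt_raw[5:8]),
        bits         = .le_uint(fmt_raw[15:16]))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size)
        stop("truncated WAV data chunk in ", path, call. = FALSE)
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV file (missing fmt/data chunk): ", path, call. = FALSE)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (only PCM/float supported): ", path,
         call. = FALSE)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768,
    "24" = .read_int24(data_raw, n) / 8388608,
    "32" = if (fmt$audio_format == 3L)
             readBin(data_raw, "double", n, 4, endian = "little")
           else
             readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648,
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE))

  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV; keeping first channel only")
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  waveform_record(x, fmt$rate_hz)
}

.le_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

.read_int24 <- function(raw, n_total) {
  n <- n_total
  i <- (seq_len(n) - 1L) * 3L
  v <- as.numeric(raw[i + 1L]) + 256 * as.numeric(raw[i + 2L]) +
    65536 * as.numeric(raw[i + 3L])
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write a 16-bit PCM mono WAV file
#'
#' Samples outside [-1, 1] are clipped; quantization is round-to-nearest,
#' so a write/read round trip deviates by at most 1/32768 per sample.
#'
#' @param rec A [waveform_record()] or numeric vector.
#' @param path Output path.
#' @param rate_hz Sampling rate, required when `rec` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate_hz = NULL) {
  if (inherits(rec, "waveform_record")) {
    x <- rec$samples; rate_hz <- rec$rate_hz
  } else {
    x <- as.numeric(rec)
    if (is.null(rate_hz)) stop("rate_hz required for a bare sample vector",
                               call. = FALSE)
  }
  q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  data_size <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  .write_uint16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  .write_uint16(1L)                       # PCM
  .write_uint16(1L)                       # mono
  writeBin(as.integer(rate_hz), con, 4, endian = "little")
  writeBin(as.integer(rate_hz * 2L), con, 4, endian = "little")  # byte rate
  .write_uint16(2L)                       # block align
  .write_uint16(16L)                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}
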