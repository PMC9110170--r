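# Minimal mono WAV I/O. No audio package ships with the target image, so the
# two PCM layouts the toolkit needs (16-bit integer, 32-bit IEEE float) are
# read and written directly. Samples are unitless amplitudes in [-1, 1].

#' Read a mono WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit mono files. Multichannel input is
#' rejected with guidance to downmix first.
#'
#' @param path file path.
#' @return A list with `samples` (numeric in `[-1, 1]`) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_mf("cannot read WAV file '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_mf("'%s' is not a RIFF/WAVE file", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        sample_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, endian = "little"))
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (id == "data") {
      if (is.null(fmt)) stop_mf("'%s': data chunk before fmt chunk", path)
      if (fmt$channels != 1L)
        stop_mf("'%s' has %d channels; mono required (downmix first)",
                path, fmt$channels)
      n <- size %/% (fmt$bits %/% 8L)
      data <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, 2L, signed = TRUE, endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        readBin(con, "double", n, 4L, endian = "little")
      } else {
        stop_mf("'%s': unsupported WAV encoding (format %d, %d bits)",
                path, fmt$audio_format, fmt$bits)
      }
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(data)) stop_mf("'%s' has no data chunk (corrupt WAV?)", path)
  list(samples = data, sample_rate = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric amplitudes; clipped to `[-1, 1]` for PCM output.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  if (!bits %in% c(16L, 32L)) stop_mf("bits must be 16 or 32")
  if (any(!is.finite(samples))) stop_mf("samples must be finite")
  n <- length(samples)
  bytes <- n * (bits %/% 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(if (bits == 16L) 1L else 3L, 1L), con, 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * bits / 8), con, 4L, endian = "little")
  writeBin(c(as.integer(bits %/% 8L), as.integer(bits)), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, 4L, endian = "little")
  if (bits == 16L) {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, 2L, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4L, endian = "little")
  }
  invisible(path)
}
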