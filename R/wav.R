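# Minimal RIFF/WAVE I/O (16-bit PCM, mono). No audio package ships with the
# supported toolchain, and the subset of WAV used here is tiny, so the format
# is read and written directly.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped.
#'
#' @param samples numeric vector of audio samples.
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_pcg("`samples` must be a non-empty numeric vector")
  if (rate <= 0) stop_pcg("`rate` must be positive")
  x <- pmax(-1, pmin(1, as.numeric(samples)))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, scaled to `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_pcg("not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_pcg("not a WAVE file: %s", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop_pcg("only PCM WAV is supported")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(rate) || is.null(samples)) stop_pcg("malformed WAV: %s", path)
  if (channels != 1L) stop_pcg("only mono WAV is supported")
  if (bits != 16L) stop_pcg("only 16-bit PCM WAV is supported")
  list(samples = samples / 32767, rate = rate)
}
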