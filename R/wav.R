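# Minimal RIFF/PCM WAV support. Only what the tone pipeline needs: 16-bit
# (and 8/32-bit) integer PCM, mono preferred, stereo downmixed with a warning.

#' Read a RIFF PCM WAV file
#'
#' Reads an uncompressed PCM WAV file and returns normalized samples in
#' \[-1, 1\]. Stereo (or higher channel count) input is downmixed to mono by
#' channel averaging, with a warning.
#'
#' @param path path to a `.wav` file.
#' @return list with `samples` (numeric vector in \[-1,1\]) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), "not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), "not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      extra <- size - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  assert_that(!is.null(fmt) && !is.null(data_raw), "missing fmt/data chunk: ", path)
  assert_that(fmt$audio_format == 1L, "only PCM (format 1) WAV supported")

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, size = 1, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                              endian = "little")) / 32768,
    "32" = as.numeric(readBin(data_raw, "integer", n, size = 4, signed = TRUE,
                              endian = "little")) / 2147483648,
    stop_invalid("unsupported PCM bit depth: ", fmt$bits)
  )
  if (fmt$n_channels > 1L) {
    warning("downmixing ", fmt$n_channels, "-channel WAV to mono: ", path)
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector; values are clipped to \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
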