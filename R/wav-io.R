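#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file containing uncompressed integer PCM samples and
#' returns an [audio_clip]. Samples are rescaled to `[-1, 1]` by dividing by
#' `2^(bits-1)`; multi-channel input is downmixed to mono by averaging the
#' channels sample-wise.
#'
#' @param path Path to a `.wav` file.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate` and `source_id` (the file name without extension).
#' @seealso [write_wav()], [frame_signal()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      n_channels   <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      sample_rate  <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
      if (audio_format != 1L)
        stop("unsupported WAV encoding (only integer PCM is handled): format tag ", audio_format)
      fmt <- list(channels = n_channels, sample_rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      bytes_per <- fmt$bits / 8
      n <- size %/% bytes_per
      if (fmt$bits == 8) {
        raw8 <- readBin(con, "integer", n, size = 1, signed = FALSE)
        samples <- (raw8 - 128) / 128
      } else if (fmt$bits == 16) {
        raw16 <- readBin(con, "integer", n, size = 2, endian = "little", signed = TRUE)
        samples <- raw16 / 32768
      } else if (fmt$bits == 32) {
        raw32 <- readBin(con, "integer", n, size = 4, endian = "little")
        samples <- raw32 / 2147483648
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits)
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2)       # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in ", path)
  if (fmt$channels > 1) {
    m <- matrix(samples, nrow = fmt$channels)
    samples <- colMeans(m)
  }
  audio_clip(samples, fmt$sample_rate,
             source_id = sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmin(pmax(samples, -1), 32767 / 32768)
  ints <- as.integer(round(x * 32768))
  ints <- pmin(pmax(ints, -32768L), 32767L)
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                      # PCM
  writeBin(1L, con, size = 2, endian = "little")                      # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
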