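#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats this package writes:
#' mono, 16-bit integer PCM or 32-bit IEEE float.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]` for integer
#'   PCM; unscaled for float) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV is supported")
      n <- sz %/% (fmt$bits %/% 8)
      if (fmt$format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", n, 4, endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", n, 2, endian = "little") / 32768
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit)")
      }
      return(list(samples = as.numeric(x), sample_rate = fmt$sample_rate))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
}

#' Write a mono WAV file
#'
#' @param samples Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 32 (IEEE float, default; preserves amplitudes exactly) or 16
#'   (integer PCM; samples are clipped to `[-1, 1)`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 32) {
  stopifnot(bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes <- n * (bits %/% 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bits / 8), con, 4, endian = "little")
  writeBin(as.integer(bits / 8), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  } else {
    q <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}
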