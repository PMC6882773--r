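# Minimal RIFF/WAVE PCM I/O (mono, 16-bit), enough for session audio.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are expected in `[-1, 1)`; values outside are clipped with a
#' warning.  Quantization is `round(x * 32767)`.
#'
#' @param x numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, rate, path) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite audio samples")
  if (any(x < -1 | x >= 1)) {
    warning("audio samples outside [-1, 1) clipped on write")
    x <- pmin(pmax(x, -1), 32766 / 32767)
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
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
#' @return list with `samples` (numeric in `[-1, 1)`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; n_chan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      n_chan <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16L) stop("only 16-bit PCM supported")
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  if (n_chan != 1L) stop("only mono WAV supported")
  list(samples = samples / 32767, rate = rate)
}
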