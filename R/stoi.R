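# Short-time objective intelligibility (STOI), the published DFT-based
# measure: 10 kHz reference rate, 256-sample frames, 15 one-third-octave
# bands from 150 Hz, 384 ms analysis segments, -15 dB clipping, 40 dB
# silent-frame exclusion.  Ported here because the measure itself is an
# established external quantity, not a tunable part of the decoder.

.STOI_FS <- 10000
.STOI_FRAME <- 256L
.STOI_NFFT <- 512L
.STOI_NBANDS <- 15L
.STOI_MINFREQ <- 150
.STOI_N <- 30L          # frames per analysis segment (384 ms)
.STOI_BETA <- -15       # lower signal-to-distortion bound, dB
.STOI_DYN <- 40         # speech dynamic range for silence removal, dB

# One-third-octave band matrix over the one-sided DFT bins.
.third_octave_bands <- function() {
  f <- (0:(.STOI_NFFT / 2)) * .STOI_FS / .STOI_NFFT
  k <- 0:(.STOI_NBANDS - 1)
  lo <- .STOI_MINFREQ * 2^((2 * k - 1) / 6)
  hi <- .STOI_MINFREQ * 2^((2 * k + 1) / 6)
  ob <- matrix(0, .STOI_NBANDS, length(f))
  for (i in seq_len(.STOI_NBANDS)) {
    a <- which.min((f - lo[i])^2)
    b <- which.min((f - hi[i])^2)
    ob[i, a:(b - 1)] <- 1
  }
  ob
}

.stoi_frames <- function(x, hop = .STOI_FRAME / 2) {
  n <- (length(x) - .STOI_FRAME) %/% hop + 1
  starts <- (seq_len(n) - 1) * hop
  matrix(x[outer(seq_len(.STOI_FRAME), starts, `+`)], .STOI_FRAME, n)
}

#' Short-time objective intelligibility of a degraded signal
#'
#' Computes the standard STOI score of `recon` given the clean reference
#' `orig`: both are resampled to 10 kHz, frames in which the clean signal
#' falls more than 40 dB below its loudest frame are removed from both,
#' and the mean clipped correlation of one-third-octave band envelopes
#' over 384 ms segments is returned.
#'
#' @param orig clean reference waveform.
#' @param recon degraded/reconstructed waveform, same length and rate.
#' @param rate sampling rate of both inputs in Hz.
#' @return STOI score, approximately in `[0, 1]`.
#' @export
compute_stoi <- function(orig, recon, rate = 16000) {
  if (length(orig) != length(recon))
    stop("signals must have equal length")
  x <- resample_signal(orig, rate, .STOI_FS)
  y <- resample_signal(recon, rate, .STOI_FS)
  w <- .hann_sym(.STOI_FRAME)
  hop <- .STOI_FRAME / 2
  if (length(x) < .STOI_FRAME * .STOI_N)
    stop("signals shorter than one STOI analysis segment")
  xf <- .stoi_frames(x) * w
  yf <- .stoi_frames(y) * w
  en <- 20 * log10(sqrt(colSums(xf^2)) + 1e-30)
  keep <- en > max(en) - .STOI_DYN
  xf <- xf[, keep, drop = FALSE]; yf <- yf[, keep, drop = FALSE]
  # overlap-add the retained frames back into continuous signals
  ola <- function(fr) {
    out <- numeric((ncol(fr) - 1) * hop + .STOI_FRAME)
    for (i in seq_len(ncol(fr))) {
      a <- (i - 1) * hop + 1
      out[a:(a + .STOI_FRAME - 1)] <- out[a:(a + .STOI_FRAME - 1)] + fr[, i]
    }
    out
  }
  x <- ola(xf); y <- ola(yf)
  # band envelopes from the windowed STFT
  spec <- function(s) {
    fr <- .stoi_frames(s) * w
    fr <- rbind(fr, matrix(0, .STOI_NFFT - .STOI_FRAME, ncol(fr)))
    Mod(mvfft(fr))[1:(.STOI_NFFT / 2 + 1), , drop = FALSE]
  }
  ob <- .third_octave_bands()
  X <- sqrt(ob %*% spec(x)^2)
  Y <- sqrt(ob %*% spec(y)^2)
  m <- ncol(X)
  if (m < .STOI_N) stop("too few voiced frames for a STOI segment")
  cl <- 10^(-.STOI_BETA / 20)
  total <- 0; count <- 0
  for (seg_end in .STOI_N:m) {
    xs <- X[, (seg_end - .STOI_N + 1):seg_end, drop = FALSE]
    ys <- Y[, (seg_end - .STOI_N + 1):seg_end, drop = FALSE]
    alpha <- sqrt(rowSums(xs^2) / (rowSums(ys^2) + 1e-30))
    yn <- pmin(ys * alpha, xs * (1 + cl))
    xc <- xs - rowMeans(xs)
    yc <- yn - rowMeans(yn)
    num <- rowSums(xc * yc)
    den <- sqrt(rowSums(xc^2) * rowSums(yc^2)) + 1e-30
    total <- total + sum(num / den)
    count <- count + .STOI_NBANDS
  }
  total / count
}
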