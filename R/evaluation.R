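# Evaluation: log-mel spectrograms, per-word Pearson correlations,
# randomized-selection chance level, empirical significance tiers, and
# the logistic mapping between STOI and transcription intelligibility.

MEL_EPS <- 1e-10

# Stevens mel scale.
.hz2mel <- function(f) 2595 * log10(1 + f / 700)
.mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

# 40 overlapping triangular filters on the mel scale over [0, fmax],
# rows = filters, cols = FFT bins (0..nfft/2).
mel_filterbank <- function(n_mels = 40, nfft = 1024, rate = 16000,
                           fmax = rate / 2) {
  pts <- .mel2hz(seq(.hz2mel(0), .hz2mel(fmax), length.out = n_mels + 2))
  bins <- 0:(nfft / 2) * rate / nfft
  fb <- matrix(0, n_mels, length(bins))
  for (j in seq_len(n_mels)) {
    lo <- pts[j]; ce <- pts[j + 1]; hi <- pts[j + 2]
    up <- (bins - lo) / (ce - lo)
    dn <- (hi - bins) / (hi - ce)
    fb[j, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "centers") <- pts[2:(n_mels + 1)]
  fb
}

#' Log-mel spectrogram of a 16 kHz waveform
#'
#' Magnitude short-time spectrum in 50 ms Hann windows at a 10 ms hop,
#' compressed through 40 overlapping triangular mel-scale filters spanning
#' 0–8 kHz, then `log(x + 1e-10)`.
#'
#' @param x numeric waveform.
#' @param rate sampling rate (must be 16000).
#' @return object of class `b2s_mel`: list with `values` (frames x 40),
#'   `frame_times` (window centers, s) and `centers` (filter center
#'   frequencies, Hz).
#' @export
mel_spectrogram <- function(x, rate = 16000) {
  if (rate != UNIT_RATE) stop("mel_spectrogram expects 16 kHz input")
  wl <- round(0.050 * rate)           # 800
  hop <- round(0.010 * rate)          # 160
  if (length(x) < wl) stop("waveform shorter than one 50 ms window")
  nfft <- 1024
  nf <- (length(x) - wl) %/% hop + 1
  starts <- (seq_len(nf) - 1) * hop
  idx <- outer(seq_len(wl), starts, `+`)
  frames <- matrix(x[idx], wl, nf) * .hann_sym(wl)
  frames <- rbind(frames, matrix(0, nfft - wl, nf))
  spec <- Mod(mvfft(frames))[1:(nfft / 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(40, nfft, rate)
  m <- log(fb %*% spec + MEL_EPS)
  structure(list(values = t(m),
                 frame_times = (starts + wl / 2) / rate,
                 centers = attr(fb, "centers")),
            class = "b2s_mel")
}

#' Per-word spectral correlations between original and reconstruction
#'
#' Both waveforms are transformed to log-mel spectrograms; for every word,
#' frames whose centers lie in `[onset, offset)` are compared via the
#' Pearson correlation of each of the 40 coefficients across frames.  A
#' coefficient with zero variance within a word is undefined (NA) and
#' excluded from that word's mean.  Words are weighted equally in the
#' grand mean.
#'
#' @param orig,recon equal-length 16 kHz waveforms.
#' @param words data.frame with `label`, `onset`, `offset` columns.
#' @param rate sampling rate (16000).
#' @return object of class `b2s_corr_report`: list with `per_word`
#'   (data.frame: label, onset, offset, n_frames, mean_r), `coef_r`
#'   (words x 40 matrix), `grand_mean_r`.
#' @export
word_correlations <- function(orig, recon, words, rate = 16000) {
  if (length(orig) != length(recon))
    stop("original and reconstruction differ in length")
  mo <- mel_spectrogram(orig, rate)
  mr <- mel_spectrogram(recon, rate)
  .word_correlations_mel(mo, mr, words)
}

# Shared core so the randomization baseline can reuse the original's mel.
.word_correlations_mel <- function(mo, mr, words) {
  nw <- nrow(words)
  coef_r <- matrix(NA_real_, nw, 40)
  n_frames <- integer(nw)
  for (i in seq_len(nw)) {
    sel <- mo$frame_times >= words$onset[i] & mo$frame_times < words$offset[i]
    n_frames[i] <- sum(sel)
    if (n_frames[i] < 3) next
    a <- mo$values[sel, , drop = FALSE]
    b <- mr$values[sel, , drop = FALSE]
    sda <- apply(a, 2, sd); sdb <- apply(b, 2, sd)
    ok <- sda > 0 & sdb > 0
    if (any(ok))
      coef_r[i, ok] <- vapply(which(ok),
                              function(j) cor(a[, j], b[, j]), 0)
  }
  mean_r <- rowMeans(coef_r, na.rm = TRUE)
  mean_r[is.nan(mean_r)] <- NA_real_
  structure(list(
    per_word = data.frame(label = words$label, onset = words$onset,
                          offset = words$offset, n_frames = n_frames,
                          mean_r = mean_r),
    coef_r = coef_r,
    grand_mean_r = mean(mean_r, na.rm = TRUE)
  ), class = "b2s_corr_report")
}

#' Randomized-selection chance baseline
#'
#' Instead of the most similar unit, each repetition draws one uniformly
#' random training unit per test frame (with replacement), overlap-adds
#' them exactly as real decoding does, and records the grand-mean per-word
#' correlation against the original audio.  The maximum of the resulting
#' distribution is the chance level.
#'
#' @param db a `b2s_unitdb` of training units.
#' @param frame_times test frame centers (one random unit drawn per frame).
#' @param words word events evaluated, as in [word_correlations()].
#' @param orig original 16 kHz waveform (defines the output duration).
#' @param n_reps number of randomizations (default 1000).
#' @param seed RNG seed for reproducible draws.
#' @return object of class `b2s_null`: list with `values` (n_reps
#'   grand-mean r), `chance_level` (their maximum), `n_reps`, `seed`.
#' @export
randomization_baseline <- function(db, frame_times, words, orig,
                                   n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  dur <- length(orig) / UNIT_RATE
  mo <- mel_spectrogram(orig, UNIT_RATE)
  n_units <- ncol(db$units$samples)
  vals <- .with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      pick <- sample.int(n_units, length(frame_times), replace = TRUE)
      recon <- overlap_add(db$units$samples[, pick, drop = FALSE],
                           frame_times, dur)
      .word_correlations_mel(mo, mel_spectrogram(recon, UNIT_RATE),
                             words)$grand_mean_r
    }, 0)
  })
  structure(list(values = vals, chance_level = max(vals),
                 n_reps = n_reps, seed = seed),
            class = "b2s_null")
}

#' Empirical significance tier against a randomization distribution
#'
#' The observed grand-mean correlation earns a tier when it is strictly
#' larger than the corresponding fraction of the randomized controls:
#' larger than 95, 99 or 99.9% of them.
#'
#' @param observed observed grand-mean correlation.
#' @param dist a `b2s_null` or numeric vector of null values.
#' @return one of `"n.s."`, `"95%"`, `"99%"`, `"99.9%"`.
#' @export
empirical_significance <- function(observed, dist) {
  vals <- if (inherits(dist, "b2s_null")) dist$values else as.numeric(dist)
  if (!length(vals)) stop("empty randomization distribution")
  s <- sort(vals)
  n <- length(s)
  tier <- "n.s."
  for (q in c(0.95, 0.99, 0.999)) {
    if (observed > s[ceiling(q * n)])
      tier <- c("95%", "99%", "99.9%")[match(q, c(0.95, 0.99, 0.999))]
  }
  tier
}

# Logistic constants linking STOI (0-100 scale) to transcription
# intelligibility: STOI = 100 / (1 + exp(a*d + b)).
STOI_A <- -13.1903
STOI_B <- 6.5192

#' Map a STOI score to subjective intelligibility probability
#'
#' Inverts the logistic fit `STOI = 100 / (1 + exp(a d + b))`
#' (a = −13.1903, b = 6.5192), in which STOI enters on a 0–100 scale:
#' `d = (ln(100 / (100 stoi) − 1) − b) / a` for a 0–1 `stoi`.  The result
#' is the expected fraction of words transcribed correctly; it is clamped
#' to [0, 1], with stoi = 0 and 1 mapping to the limits 0 and 1.
#'
#' @param stoi STOI score(s) in `[0, 1]`.
#' @return intelligibility probability `d` in `[0, 1]`.
#' @export
stoi_to_intelligibility <- function(stoi) {
  d <- ifelse(stoi <= 0, 0,
       ifelse(stoi >= 1, 1,
              (log(100 / (100 * stoi) - 1) - STOI_B) / STOI_A))
  pmin(1, pmax(0, d))
}

#' Map an intelligibility probability back to a STOI score
#'
#' Forward logistic `stoi = 1 / (1 + exp(a d + b))` (0–1 scale); inverse
#' of [stoi_to_intelligibility()] on (0, 1).
#'
#' @param d intelligibility probability in `[0, 1]`.
#' @return STOI score in `(0, 1)`.
#' @export
intelligibility_to_stoi <- function(d) {
  1 / (1 + exp(STOI_A * d + STOI_B))
}
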