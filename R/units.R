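# Speech units: 150 ms Hanning-windowed audio snippets at 16 kHz, one per
# 10 ms neural frame, and overlap-add reconstruction from unit sequences.

UNIT_RATE <- 16000L
UNIT_LEN  <- 2400L    # 0.150 s * 16 kHz

#' Extract Hanning-windowed speech units aligned to frame times
#'
#' Audio is resampled to 16 kHz; unit i is the 150 ms (2400-sample) slice
#' centered on `round(frame_times[i] * 16000)`, multiplied by a symmetric
#' Hanning window so both endpoints taper to zero.  Frame times whose
#' window would cross the audio boundary must already have been dropped
#' (see [usable_frames()]); otherwise this is an error.
#'
#' @param audio numeric sample vector.
#' @param audio_rate sampling rate of `audio` in Hz.
#' @param frame_times frame center times in seconds, 10 ms apart.
#' @return object of class `b2s_units`: list with `samples`
#'   (2400 x n matrix, windowed), `center_times`, `rate` (16000).
#' @export
extract_units <- function(audio, audio_rate, frame_times) {
  a16 <- resample_signal(audio, audio_rate, UNIT_RATE)
  centers <- round(frame_times * UNIT_RATE) + 1L       # 1-based
  half <- UNIT_LEN %/% 2
  if (length(centers) &&
      (min(centers) - half < 1 || max(centers) + half - 1 > length(a16)))
    stop("frame window outside audio extent; boundary frames must be dropped")
  w <- .hann_sym(UNIT_LEN)
  offs <- seq(-half, half - 1)
  units <- matrix(0, UNIT_LEN, length(centers))
  if (length(centers)) {
    idx <- outer(offs, centers, `+`)
    units <- matrix(a16[idx], UNIT_LEN, length(centers)) * w
  }
  structure(list(samples = units, center_times = frame_times,
                 rate = UNIT_RATE),
            class = "b2s_units")
}

#' Overlap-add a sequence of speech units into a waveform
#'
#' The output buffer (16 kHz) is initialized to zero and each already
#' windowed unit is added at its frame's center position — plain summation,
#' no re-windowing and no gain renormalization.  At the 10 ms hop, 15
#' Hanning windows overlap every sample, so a constant source reproduces at
#' a steady-state gain of 7.5 (the window sum); see [window_sum_gain()].
#'
#' @param units a `b2s_units` (or 2400 x n matrix) of selected units, one
#'   per frame.
#' @param frame_times center times of the selected frames, in seconds.
#' @param out_duration output duration in seconds.
#' @param normalize_gain divide by the window-sum envelope (off by
#'   default; evaluation is spectral and gain-robust).
#' @return numeric waveform of length `round(out_duration * 16000)`.
#' @export
overlap_add <- function(units, frame_times, out_duration,
                        normalize_gain = FALSE) {
  m <- if (inherits(units, "b2s_units")) units$samples else as.matrix(units)
  if (ncol(m) != length(frame_times))
    stop("unit count (", ncol(m), ") != frame count (", length(frame_times), ")")
  if (nrow(m) != UNIT_LEN) stop("units must have ", UNIT_LEN, " samples")
  n_out <- round(out_duration * UNIT_RATE)
  out <- numeric(n_out)
  half <- UNIT_LEN %/% 2
  centers <- round(frame_times * UNIT_RATE) + 1L
  for (i in seq_along(centers)) {
    a <- centers[i] - half; b <- centers[i] + half - 1L
    if (a < 1 || b > n_out) stop("unit ", i, " extends outside the output buffer")
    out[a:b] <- out[a:b] + m[, i]
  }
  if (normalize_gain && length(centers)) {
    env <- numeric(n_out)
    w <- .hann_sym(UNIT_LEN)
    for (i in seq_along(centers)) {
      a <- centers[i] - half; b <- centers[i] + half - 1L
      env[a:b] <- env[a:b] + w
    }
    out <- out / pmax(env, 1e-3)
  }
  out
}

#' Steady-state gain of the 150 ms / 10 ms Hanning overlap-add
#'
#' Sum of the symmetric 2400-sample Hanning window sampled at the
#' 160-sample hop — the constant factor by which an oracle reconstruction
#' scales the original signal.  Approximately 7.5, with well under 1%
#' ripple across hop phases.
#'
#' @param phase hop phase offset in samples (0 to 159).
#' @return numeric gain.
#' @export
window_sum_gain <- function(phase = 0) {
  w <- .hann_sym(UNIT_LEN)
  hop <- UNIT_RATE / 100
  idx <- seq(1 + phase, UNIT_LEN, by = hop)
  sum(w[idx])
}

#' Build a unit-selection database
#'
#' Pairs each training frame's (normalized, PCA-projected) feature vector
#' with its 150 ms speech unit and precomputes the Euclidean norm of every
#' feature row, so cosine similarities against the whole database reduce
#' to one matrix product at decode time.
#'
#' @param features training `b2s_features` (normalized and projected).
#' @param units training `b2s_units`, aligned one-to-one with `features`.
#' @return object of class `b2s_unitdb` with `features`, `units`, `norms`.
#' @export
unit_database <- function(features, units) {
  if (nrow(features$values) != ncol(units$samples))
    stop("feature frames (", nrow(features$values), ") != units (",
         ncol(units$samples), ")")
  if (nrow(features$values) == 0) stop("empty unit database")
  if (max(abs(features$frame_times - units$center_times)) > 1e-9)
    stop("feature frame times and unit center times differ")
  structure(list(features = features, units = units,
                 norms = sqrt(rowSums(features$values^2))),
            class = "b2s_unitdb")
}
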