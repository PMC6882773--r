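#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft filter mvfft prcomp rnorm runif sd setNames
#' @importFrom utils getFromNamespace read.delim write.table
NULL

# Reduce p/q to lowest terms for polyphase resampling.
.ratio <- function(to, from) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  stopifnot(to == round(to), from == round(from))
  d <- g(to, from)
  c(p = to / d, q = from / d)
}

#' Resample a signal to a new rate
#'
#' Rational-ratio resampling (upfirdn): zero-stuff by p, anti-alias with a
#' linear-phase Hamming-windowed FIR low-pass at the tighter of the two
#' Nyquist limits, compensate the group delay, and keep every q-th sample.
#' Rates must be integers (Hz).
#'
#' @param x numeric vector.
#' @param from,to source and target sampling rates in Hz.
#' @return numeric vector of length `round(length(x) * to / from)`.
#' @export
resample_signal <- function(x, from, to) {
  x <- as.numeric(x)
  if (from == to) return(x)
  r <- .ratio(to, from)
  p <- r[["p"]]; q <- r[["q"]]
  n_out <- round(length(x) * (to / from))
  n_taps <- 2L * 10L * max(p, q) + 1L          # ~10 zero crossings per side
  h <- p * signal::fir1(n_taps - 1L, 1 / max(p, q), "low")
  up <- numeric(length(x) * p)
  up[seq(1, length(up), by = p)] <- x
  gd <- (n_taps - 1L) / 2L
  yf <- signal::fftfilt(h, c(up, numeric(gd)))
  yf <- yf[(gd + 1L):length(yf)]
  y <- yf[seq(1, length(up), by = q)]
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

# Symmetric Hann window, zero at both endpoints.
.hann_sym <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Run `expr` under a private RNG stream without disturbing the caller's.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Deterministic 31-bit sub-seed from a base seed and a string tag.
.subseed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Frame-time grid at a fixed frameshift
#'
#' Frame centers `0, frameshift, 2*frameshift, ...` strictly below
#' `duration`.  A 500 s recording at the default 10 ms frameshift yields
#' 50,000 frames, one speech unit each before boundary dropping.
#'
#' @param duration recording duration in seconds.
#' @param frameshift hop between frames in seconds (default 0.01).
#' @return numeric vector of frame center times in seconds.
#' @export
frame_grid <- function(duration, frameshift = 0.01) {
  n <- floor(duration / frameshift + 1e-9)
  (seq_len(n) - 1) * frameshift
}

#' Frames usable by both the neural context window and the audio unit window
#'
#' Frames whose 450 ms neural context (centered or causal) or whose 150 ms
#' audio unit window would extend beyond the recording are dropped, so
#' features and speech units stay aligned one-to-one.
#'
#' @param duration recording duration in seconds.
#' @param mode `"centered"` (window `[t-0.225, t+0.225)`) or `"causal"`
#'   (window `(t-0.450, t]`).
#' @param frameshift hop in seconds.
#' @return numeric vector of usable frame center times.
#' @export
usable_frames <- function(duration, mode = c("centered", "causal"),
                          frameshift = 0.01) {
  mode <- match.arg(mode)
  t <- frame_grid(duration, frameshift)
  ok_audio <- t - 0.075 >= 0 & t + 0.075 <= duration
  ok_neural <- if (mode == "centered")
    t - 0.225 >= 0 & t + 0.225 <= duration
  else
    t - 0.450 >= 0 & t <= duration
  t[ok_audio & ok_neural]
}
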