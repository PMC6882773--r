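# Neural feature extraction: raw multichannel ECoG -> log high-gamma
# band power at 600 Hz -> context feature vectors at a 10 ms frame rate.

LOG_FLOOR <- 1e-10   # floor under the squared signal before the log

#' Log high-gamma band power of a multichannel neural recording
#'
#' Per channel: linear detrend, anti-aliased polyphase resampling to
#' 600 Hz, zero-phase (forward-backward) elliptic filtering — high-pass at
#' 70 Hz (order 13), low-pass at 170 Hz (order 14) and a band-stop at
#' 118–122 Hz (order 13) suppressing the first line-noise harmonic — then
#' `log(x^2 + 1e-10)`.
#'
#' @param neural channels x samples numeric matrix.
#' @param rate sampling rate of `neural` in Hz; must be at least 600.
#' @return object of class `b2s_bandpower`: list with `values`
#'   (channels x samples log-power matrix), `rate` (600) and `channel_names`.
#' @export
preprocess_ecog <- function(neural, rate) {
  neural <- as.matrix(neural)
  if (any(!is.finite(neural))) stop("non-finite values in neural input")
  if (rate < 2 * 170) stop("sampling rate ", rate,
                           " Hz cannot represent the 70-170 Hz band")
  if (rate < 600) stop("rate below the 600 Hz processing rate")
  if (ncol(neural) / rate < 1) stop("need at least 1 s of data")
  fs <- 600
  cascade <- .hg_cascade(fs)
  n_out <- round(ncol(neural) * fs / rate)
  out <- matrix(0, nrow(neural), n_out)
  tt <- seq_len(ncol(neural))
  for (ch in seq_len(nrow(neural))) {
    x <- neural[ch, ]
    co <- stats::coef(stats::lsfit(tt, x))        # linear detrend
    x <- x - (co[1] + co[2] * tt)
    x <- resample_signal(x, rate, fs)
    x <- sosfiltfilt(cascade$hp, x)
    x <- sosfiltfilt(cascade$lp, x)
    x <- sosfiltfilt(cascade$stop, x)
    out[ch, ] <- log(x^2 + LOG_FLOOR)
  }
  structure(list(values = out, rate = fs,
                 channel_names = rownames(neural)),
            class = "b2s_bandpower")
}

#' Context feature vectors from log band power
#'
#' For each frame time t, a 450 ms context window of the 600 Hz log-power
#' signal — `[t - 0.225, t + 0.225)` in centered mode, `(t - 0.450, t]` in
#' causal mode — is partitioned into nine consecutive 50 ms bins and each
#' bin is mean-pooled (the 20 Hz context resolution).  Features are
#' flattened channel-major: channel c, bin k maps to column `(c-1)*9 + k`.
#' Frames whose window would cross the recording boundary are dropped.
#'
#' @param power a `b2s_bandpower` from [preprocess_ecog()].
#' @param frame_times frame center times in seconds (10 ms grid).
#' @param mode `"centered"` or `"causal"` (uses no samples after t).
#' @return object of class `b2s_features`: list with `values`
#'   (frames x n_channels*9 matrix), `frame_times` (kept frames),
#'   `n_channels`, `bins` (9), `mode`, and flags `normalized`, `projected`.
#' @export
extract_context_features <- function(power, frame_times,
                                     mode = c("centered", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(power, "b2s_bandpower"))
  fs <- power$rate
  win <- round(0.450 * fs)            # 270 samples
  bins <- 9L
  bw <- win / bins                    # 30 samples per bin
  n <- ncol(power$values)
  n_ch <- nrow(power$values)
  if (win > n) stop("context window longer than recording")
  if (!length(frame_times))
    return(.feature_matrix(matrix(0, 0, n_ch * bins), numeric(0), n_ch, mode))
  i0 <- round(frame_times * fs) + 1L  # 1-based center sample
  offs <- if (mode == "centered") seq(-win / 2, win / 2 - 1) else
    seq(-win + 1, 0)
  keep <- i0 + offs[1] >= 1 & i0 + offs[win] <= n
  i0 <- i0[keep]
  nf <- length(i0)
  vals <- matrix(0, nf, n_ch * bins)
  if (nf) {
    idx <- outer(i0, offs, `+`)                      # frames x 270
    pool <- matrix(0, win, bins)                     # mean-pooling operator
    for (k in seq_len(bins)) pool[((k - 1) * bw + 1):(k * bw), k] <- 1 / bw
    for (ch in seq_len(n_ch)) {
      m <- matrix(power$values[ch, idx], nf, win)
      vals[, (ch - 1) * bins + seq_len(bins)] <- m %*% pool
    }
  }
  .feature_matrix(vals, frame_times[keep], n_ch, mode)
}

.feature_matrix <- function(values, frame_times, n_channels, mode,
                            normalized = FALSE, projected = FALSE) {
  structure(list(values = values, frame_times = frame_times,
                 n_channels = n_channels, bins = 9L, mode = mode,
                 normalized = normalized, projected = projected),
            class = "b2s_features")
}

#' Recover the channels x bins matrix from one flattened feature vector
#'
#' Inverse of the channel-major flattening used by
#' [extract_context_features()].
#'
#' @param v feature vector of length `n_channels * 9`.
#' @param n_channels number of channels.
#' @return `n_channels` x 9 matrix.
#' @export
unflatten_features <- function(v, n_channels) {
  matrix(v, nrow = n_channels, ncol = 9, byrow = TRUE)
}

#' Fit a per-feature z-scoring normalizer
#'
#' Means and standard deviations are estimated on training frames only and
#' then applied unchanged to any matrix with the same layout, so no test
#' statistics leak into the model.
#'
#' @param features a `b2s_features` with at least 2 frames.
#' @return object of class `b2s_normalizer` with `mean` and `sd` vectors.
#' @export
fit_normalizer <- function(features) {
  x <- features$values
  if (nrow(x) < 2) stop("need >= 2 frames to fit a normalizer")
  structure(list(mean = colMeans(x),
                 sd = apply(x, 2, sd),
                 n_features = ncol(x)),
            class = "b2s_normalizer")
}

#' Apply a fitted normalizer
#'
#' Constant features (sd = 0 on the training data) map to 0: they carry no
#' information and become neutral under cosine similarity.
#'
#' @param features a `b2s_features` with the fitting layout.
#' @param normalizer a `b2s_normalizer`.
#' @return normalized `b2s_features`.
#' @export
apply_normalizer <- function(features, normalizer) {
  x <- features$values
  if (ncol(x) != normalizer$n_features)
    stop("feature layout mismatch: ", ncol(x), " columns vs ",
         normalizer$n_features, " at fit time")
  s <- normalizer$sd
  z <- sweep(x, 2, normalizer$mean)
  z <- sweep(z, 2, ifelse(s > 0, s, 1), `/`)
  z[, s == 0] <- 0
  out <- features
  out$values <- z
  out$normalized <- TRUE
  out
}

#' Fit a variance-threshold PCA projection
#'
#' Retains the smallest number k of leading principal components whose
#' cumulative explained-variance fraction reaches `threshold` (default
#' 0.70).  Fit on normalized training features only; the identical
#' compression is then applied to test data via [project_features()].
#'
#' @param features normalized `b2s_features` (>= 2 frames).
#' @param threshold fraction of total variance to retain, in (0, 1].
#' @return object of class `b2s_pca` with `mean`, `components`
#'   (features x k, orthonormal), `explained` (per-component fractions)
#'   and `threshold`.
#' @export
fit_pca <- function(features, threshold = 0.70) {
  x <- features$values
  if (nrow(x) < 2) stop("need >= 2 frames to fit PCA")
  stopifnot(threshold > 0, threshold <= 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- v / sum(v)
  k <- which(cumsum(frac) >= threshold - 1e-12)[1]
  structure(list(mean = pc$center,
                 components = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = frac[seq_len(k)],
                 threshold = threshold),
            class = "b2s_pca")
}

#' Project features onto a fitted PCA basis
#'
#' @param features normalized `b2s_features` matching the fit layout.
#' @param pca a `b2s_pca`.
#' @return projected `b2s_features` with k columns.
#' @export
project_features <- function(features, pca) {
  x <- features$values
  if (ncol(x) != nrow(pca$components))
    stop("feature layout mismatch with PCA basis")
  out <- features
  out$values <- sweep(x, 2, pca$mean) %*% pca$components
  out$projected <- TRUE
  out
}
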