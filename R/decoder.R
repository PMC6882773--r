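# Unit-selection decoding: per test frame, retrieve the training speech
# unit whose feature vector maximizes cosine similarity (target cost only;
# concatenation cost deliberately omitted, no Viterbi).

#' Cosine similarity between two feature vectors
#'
#' `dot(a, b) / (||a|| ||b||)` — invariant to positive rescaling of either
#' vector (gamma-power gain), so only the distribution of power across
#' electrodes matters.  If either norm is zero the similarity is defined
#' as 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Select the best-matching training unit for every test frame
#'
#' Exact exhaustive nearest-neighbor search under cosine similarity,
#' vectorized as a matrix product of norm-scaled rows against the
#' database's precomputed norms.  Each frame is selected independently;
#' ties break to the lowest training index, and a frame whose similarities
#' are all zero (zero-norm feature vector) selects the first unit.
#'
#' @param test `b2s_features` normalized and projected with the database's
#'   training-fold statistics.
#' @param db a `b2s_unitdb`.
#' @param block test frames are processed in blocks of this many rows to
#'   bound the similarity-matrix memory.
#' @return object of class `b2s_selection`: list with `indices` (chosen
#'   training frame per test frame) and `similarities` (the maxima).
#' @export
select_units <- function(test, db, block = 2048L) {
  x <- test$values
  if (ncol(x) != ncol(db$features$values))
    stop("test feature dimension differs from database")
  tn <- db$norms
  trn <- db$features$values / ifelse(tn > 0, tn, 1)
  trn[tn == 0, ] <- 0
  n <- nrow(x)
  idx <- integer(n); sim <- numeric(n)
  xn <- sqrt(rowSums(x^2))
  xs <- x / ifelse(xn > 0, xn, 1)
  xs[xn == 0, ] <- 0
  for (a in seq(1, max(n, 1), by = block)) {
    if (a > n) break
    b <- min(a + block - 1L, n)
    s <- xs[a:b, , drop = FALSE] %*% t(trn)
    idx[a:b] <- max.col(s, ties.method = "first")
    sim[a:b] <- s[cbind(seq_len(b - a + 1L), idx[a:b])]
  }
  structure(list(indices = idx, similarities = pmin(1, pmax(-1, sim))),
            class = "b2s_selection")
}

#' Fit a unit-selection decoding model on a training session
#'
#' Runs the full training-side chain: channel-subset restriction, log
#' high-gamma preprocessing, context feature extraction, z-scoring
#' normalizer, variance-threshold PCA, and the aligned speech-unit
#' database.  All fitted statistics are functions of this session only.
#'
#' @param train a `b2s_session`.
#' @param mode `"centered"` or `"causal"` feature context.
#' @param regions `"all"` or a subset of `c("IFG","PMv","M1v","OTHER")`.
#' @param pca_threshold PCA explained-variance threshold (default 0.70).
#' @param frame_times optional frame centers; defaults to all usable
#'   frames of the session.
#' @return object of class `b2s_model` with elements `normalizer`, `pca`,
#'   `db`, `mode`, `regions`, `channel_names`.
#' @export
fit_decoder_model <- function(train, mode = c("centered", "causal"),
                              regions = "all", pca_threshold = 0.70,
                              frame_times = NULL) {
  mode <- match.arg(mode)
  keep <- .region_channels(train, regions)
  power <- preprocess_ecog(train$neural[keep, , drop = FALSE],
                           train$neural_rate)
  dur <- session_duration(train)
  if (is.null(frame_times)) frame_times <- usable_frames(dur, mode)
  feats <- extract_context_features(power, frame_times, mode)
  norm <- fit_normalizer(feats)
  nf <- apply_normalizer(feats, norm)
  pca <- fit_pca(nf, pca_threshold)
  pf <- project_features(nf, pca)
  units <- extract_units(train$audio, train$audio_rate, pf$frame_times)
  structure(list(normalizer = norm, pca = pca,
                 db = unit_database(pf, units),
                 mode = mode, regions = regions,
                 channel_names = train$channels$name[keep]),
            class = "b2s_model")
}

.region_channels <- function(s, regions) {
  if (identical(regions, "all")) return(seq_len(nrow(s$neural)))
  bad <- setdiff(regions, REGIONS)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  keep <- which(s$channels$region %in% regions)
  if (!length(keep)) stop("channel subset is empty for regions: ",
                          paste(regions, collapse = ", "))
  keep
}

#' Decode a session into a speech waveform
#'
#' Test-side chain: preprocess the (region-restricted) neural data,
#' extract context features, apply the model's training-fold normalizer
#' and PCA, select the best-matching training unit per frame, and
#' overlap-add the retrieved units into a 16 kHz waveform aligned to
#' session time.
#'
#' @param test a `b2s_session`.
#' @param model a `b2s_model` from [fit_decoder_model()], fitted with the
#'   same mode and channel subset.
#' @param frame_times optional frame centers to decode; defaults to all
#'   usable frames.
#' @return list with `waveform` (16 kHz, spanning the test session),
#'   `selection` (a `b2s_selection`) and `frame_times`.
#' @export
decode_session <- function(test, model, frame_times = NULL) {
  keep <- .region_channels(test, model$regions)
  if (!identical(test$channels$name[keep], model$channel_names))
    stop("test session channels do not match the model's channel subset")
  power <- preprocess_ecog(test$neural[keep, , drop = FALSE],
                           test$neural_rate)
  dur <- session_duration(test)
  if (is.null(frame_times)) frame_times <- usable_frames(dur, model$mode)
  feats <- extract_context_features(power, frame_times, model$mode)
  feats <- project_features(apply_normalizer(feats, model$normalizer),
                            model$pca)
  sel <- select_units(feats, model$db)
  chosen <- model$db$units$samples[, sel$indices, drop = FALSE]
  wav <- overlap_add(chosen, feats$frame_times, dur)
  list(waveform = wav, selection = sel, frame_times = feats$frame_times)
}
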