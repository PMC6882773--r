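# Experiment orchestration: grouped 5-fold cross-validation with disjoint
# word sets, per-region decoding, and report generation.

#' Assign frames to word tokens
#'
#' @param frame_times frame centers in seconds.
#' @param words data.frame with `onset`, `offset`.
#' @return integer vector: word-token index per frame, NA for silence.
#' @export
assign_frames_to_words <- function(frame_times, words) {
  out <- rep(NA_integer_, length(frame_times))
  for (i in seq_len(nrow(words))) {
    out[frame_times >= words$onset[i] & frame_times < words$offset[i]] <- i
  }
  out
}

#' Cross-validation fold plan with disjoint word sets
#'
#' Distinct word labels (or, with `by_token = TRUE`, individual tokens)
#' are shuffled under the seed and partitioned into k near-equal groups.
#' A fold's test frames are all frames inside its test words; training
#' frames are the remaining word frames plus inter-word silence frames,
#' except silence within 150 ms of a test word, which is excluded from
#' that fold entirely so no test-adjacent audio enters the unit inventory.
#'
#' @param words data.frame with `label`, `onset`, `offset`.
#' @param frame_times frame centers the plan indexes into.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param by_token split by word token instead of by label type; used for
#'   synthetic sessions where the same label must recur across folds.
#' @return object of class `b2s_foldplan`: list with `k`, `by_token`,
#'   `frame_word` (token per frame), `folds` — each fold holding
#'   `test_labels`, `test_tokens`, `test_frames`, `train_frames` (indices
#'   into `frame_times`).
#' @export
split_folds_by_word <- function(words, frame_times, k = 5, seed = 1,
                                by_token = FALSE) {
  labs <- unique(words$label)
  if (!by_token && length(labs) < k)
    stop("need at least ", k, " distinct word labels for ", k, " folds")
  if (by_token && nrow(words) < k)
    stop("need at least ", k, " word tokens for ", k, " folds")
  frame_word <- assign_frames_to_words(frame_times, words)
  units <- if (by_token) seq_len(nrow(words)) else labs
  grp <- .with_seed(.subseed(seed, "folds"), {
    sh <- sample(units)
    split(sh, rep(seq_len(k), length.out = length(sh)))
  })
  folds <- lapply(seq_len(k), function(i) {
    test_tokens <- if (by_token) sort(grp[[i]]) else
      which(words$label %in% grp[[i]])
    test_frames <- which(frame_word %in% test_tokens)
    # silence frames near any test word are off limits for training
    near_test <- rep(FALSE, length(frame_times))
    for (tok in test_tokens)
      near_test <- near_test |
        (frame_times >= words$onset[tok] - 0.15 &
         frame_times < words$offset[tok] + 0.15)
    train_frames <- which((is.na(frame_word) & !near_test) |
                          (!is.na(frame_word) &
                           !(frame_word %in% test_tokens)))
    list(test_labels = sort(unique(words$label[test_tokens])),
         test_tokens = test_tokens,
         test_frames = test_frames,
         train_frames = train_frames)
  })
  structure(list(k = k, by_token = by_token, frame_word = frame_word,
                 frame_times = frame_times, folds = folds),
            class = "b2s_foldplan")
}

#' Cross-validation run configuration
#'
#' @param mode feature context mode, `"centered"` or `"causal"`.
#' @param regions `"all"` or a subset of region names.
#' @param k number of folds.
#' @param pca_threshold PCA explained-variance threshold.
#' @param n_null_reps randomization repetitions for the chance level
#'   (0 disables the null).
#' @param split_by_token fold words by token instead of by label.
#' @param compute_stoi also compute STOI and mapped intelligibility.
#' @param seed seed for fold shuffling and the randomization null.
#' @return object of class `b2s_runconfig`.
#' @export
run_config <- function(mode = "centered", regions = "all", k = 5,
                       pca_threshold = 0.70, n_null_reps = 0,
                       split_by_token = FALSE, compute_stoi = TRUE,
                       seed = 1) {
  if (!length(regions)) stop("regions must be non-empty")
  structure(list(mode = match.arg(mode, c("centered", "causal")),
                 regions = regions, k = k,
                 pca_threshold = pca_threshold,
                 n_null_reps = n_null_reps,
                 split_by_token = split_by_token,
                 compute_stoi = compute_stoi, seed = seed),
            class = "b2s_runconfig")
}

.subset_features <- function(f, rows) {
  out <- f
  out$values <- f$values[rows, , drop = FALSE]
  out$frame_times <- f$frame_times[rows]
  out
}

#' Run the full cross-validated decoding experiment on a session
#'
#' For each fold, normalizer, PCA and the unit database are fitted on
#' training frames only; test frames are decoded and their retrieved
#' units overlap-added into a session-long reconstruction, so every word
#' is reconstructed exactly once, from a model that never saw it.  The
#' reconstruction is then scored against the original audio (per-word
#' log-mel correlations, optional randomized-selection null and STOI).
#'
#' @param s a `b2s_session`.
#' @param config a `b2s_runconfig`.
#' @return object of class `b2s_crossval`: list with `grand_mean_r`,
#'   `report` (a `b2s_corr_report`), `recon` and `orig16` (16 kHz
#'   waveforms), `folds` (per-fold summaries), `plan`, `null`
#'   (`b2s_null` or NULL), `significance`, `stoi`, `intelligibility`,
#'   `config`.
#' @export
crossval_run <- function(s, config = run_config()) {
  validate_session(s)
  keep <- .region_channels(s, config$regions)
  power <- preprocess_ecog(s$neural[keep, , drop = FALSE], s$neural_rate)
  dur <- session_duration(s)
  ft <- usable_frames(dur, config$mode)
  raw <- extract_context_features(power, ft, config$mode)
  ft <- raw$frame_times
  units_all <- extract_units(s$audio, s$audio_rate, ft)
  orig16 <- resample_signal(s$audio, s$audio_rate, UNIT_RATE)
  length(orig16) <- round(dur * UNIT_RATE)
  orig16[is.na(orig16)] <- 0

  plan <- split_folds_by_word(s$words, ft, k = config$k,
                              seed = config$seed,
                              by_token = config$split_by_token)
  recon <- numeric(length(orig16))
  fold_info <- vector("list", plan$k)
  for (i in seq_len(plan$k)) {
    fo <- plan$folds[[i]]
    if (length(fo$train_frames) < 2 || !length(fo$test_frames)) {
      fold_info[[i]] <- list(fold = i, n_test = length(fo$test_frames),
                             skipped = TRUE)
      next
    }
    trn <- .subset_features(raw, fo$train_frames)
    tst <- .subset_features(raw, fo$test_frames)
    norm <- fit_normalizer(trn)
    pca <- fit_pca(apply_normalizer(trn, norm), config$pca_threshold)
    trn_p <- project_features(apply_normalizer(trn, norm), pca)
    tst_p <- project_features(apply_normalizer(tst, norm), pca)
    db_units <- units_all
    db_units$samples <- units_all$samples[, fo$train_frames, drop = FALSE]
    db_units$center_times <- units_all$center_times[fo$train_frames]
    db <- unit_database(trn_p, db_units)
    sel <- select_units(tst_p, db)
    recon <- recon + overlap_add(
      db$units$samples[, sel$indices, drop = FALSE],
      tst_p$frame_times, dur)
    fold_info[[i]] <- list(fold = i, n_train = length(fo$train_frames),
                           n_test = length(fo$test_frames),
                           n_components = ncol(pca$components),
                           test_labels = fo$test_labels,
                           mean_similarity = mean(sel$similarities),
                           skipped = FALSE)
  }

  report <- word_correlations(orig16, recon, s$words)

  null <- NULL; signif <- NULL
  if (config$n_null_reps > 0) {
    mo <- mel_spectrogram(orig16, UNIT_RATE)
    null_vals <- .with_seed(.subseed(config$seed, "null"), {
      vapply(seq_len(config$n_null_reps), function(rep) {
        rr <- numeric(length(orig16))
        for (i in seq_len(plan$k)) {
          fo <- plan$folds[[i]]
          if (length(fo$train_frames) < 2 || !length(fo$test_frames)) next
          pick <- fo$train_frames[sample.int(length(fo$train_frames),
                                             length(fo$test_frames),
                                             replace = TRUE)]
          rr <- rr + overlap_add(units_all$samples[, pick, drop = FALSE],
                                 ft[fo$test_frames], dur)
        }
        .word_correlations_mel(mo, mel_spectrogram(rr, UNIT_RATE),
                               s$words)$grand_mean_r
      }, 0)
    })
    null <- structure(list(values = null_vals,
                           chance_level = max(null_vals),
                           n_reps = config$n_null_reps,
                           seed = config$seed),
                      class = "b2s_null")
    signif <- empirical_significance(report$grand_mean_r, null)
  }

  stoi <- NULL; intel <- NULL
  if (isTRUE(config$compute_stoi)) {
    stoi <- compute_stoi(orig16, recon, UNIT_RATE)
    intel <- stoi_to_intelligibility(max(0, min(1, stoi)))
  }

  structure(list(grand_mean_r = report$grand_mean_r, report = report,
                 recon = recon, orig16 = orig16, folds = fold_info,
                 plan = plan, null = null, significance = signif,
                 stoi = stoi, intelligibility = intel, config = config),
            class = "b2s_crossval")
}

#' @export
print.b2s_crossval <- function(x, ...) {
  cat("<b2s_crossval>\n")
  cat(sprintf("  mode=%s regions=%s folds=%d\n", x$config$mode,
              paste(x$config$regions, collapse = "+"), x$plan$k))
  cat(sprintf("  grand mean mel r = %.3f over %d words\n",
              x$grand_mean_r, nrow(x$report$per_word)))
  if (!is.null(x$null))
    cat(sprintf("  chance level (max of %d randomizations) = %.3f [%s]\n",
                x$null$n_reps, x$null$chance_level, x$significance))
  if (!is.null(x$stoi))
    cat(sprintf("  STOI = %.3f -> intelligibility %.0f%%\n",
                x$stoi, 100 * x$intelligibility))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param cv a `b2s_crossval`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_crossval_report <- function(cv, path) {
  out <- list(
    session = list(n_words = nrow(cv$report$per_word)),
    config = unclass(cv$config),
    grand_mean_r = cv$grand_mean_r,
    per_word = cv$report$per_word,
    chance_level = if (!is.null(cv$null)) cv$null$chance_level else NULL,
    significance = cv$significance,
    stoi = cv$stoi,
    intelligibility = cv$intelligibility)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
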