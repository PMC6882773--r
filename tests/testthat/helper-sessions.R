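# Shared fixtures, all built in code.  Heavy objects (synthetic sessions,
# cross-validation runs, the randomization null) are memoized so every
# test file sees the same study conditions without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

INVENTORY10 <- c("bat", "bed", "cat", "dog", "fan",
                 "hat", "kit", "lap", "mud", "pig")

# The study conditions for end-to-end synthetic runs: 60 s, 16 channels,
# 10-label CVC inventory with 3 tokens per label, token-split 5-fold CV.
study_config <- function(coupling, seed = 11) {
  sim_config(n_words = 30, n_channels = 16,
             region_plan = c(IFG = 4, PMv = 5, M1v = 5, OTHER = 2),
             word_inventory = INVENTORY10,
             coupling = coupling, seed = seed)
}

study_session <- function(coupling) {
  memo(sprintf("sess_c%g", coupling), simulate_session(study_config(coupling)))
}

study_cv <- function(coupling, mode = "centered", n_null_reps = 0,
                     regions = "all", with_stoi = FALSE) {
  key <- sprintf("cv_c%g_%s_n%d_%s", coupling, mode, n_null_reps,
                 paste(regions, collapse = "+"))
  memo(key, crossval_run(
    study_session(coupling),
    run_config(mode = mode, regions = regions, split_by_token = TRUE,
               n_null_reps = n_null_reps, compute_stoi = with_stoi,
               seed = 5)))
}

# A small quick session for structural tests.
tiny_session <- function(seed = 3, n_words = 6, coupling = 1) {
  memo(sprintf("tiny_%d_%d_%g", seed, n_words, coupling), {
    cfg <- sim_config(n_words = n_words, n_channels = 6,
                      region_plan = c(IFG = 2, PMv = 2, M1v = 2),
                      word_inventory = c("bat", "dog", "kit"),
                      coupling = coupling, seed = seed)
    simulate_session(cfg)
  })
}

# Band-power object with reproducible random content, without filtering.
fake_bandpower <- function(n_channels, duration, seed = 1) {
  n <- round(duration * 600)
  vals <- matrix(0, n_channels, n)
  set.seed(seed)
  vals[] <- rnorm(n_channels * n)
  structure(list(values = vals, rate = 600,
                 channel_names = sprintf("OTHER_%d", seq_len(n_channels))),
            class = "b2s_bandpower")
}

# Features object straight from a matrix (layout-compatible container).
fake_features <- function(m, frame_times = seq_len(nrow(m)) * 0.01) {
  structure(list(values = m, frame_times = frame_times,
                 n_channels = NA_integer_, bins = 9L, mode = "centered",
                 normalized = TRUE, projected = TRUE),
            class = "b2s_features")
}

# Unit database over arbitrary feature rows with dummy (zero) audio units.
fake_db <- function(feature_matrix) {
  ft <- seq_len(nrow(feature_matrix)) * 0.01 + 0.075
  units <- structure(list(samples = matrix(0, 2400, nrow(feature_matrix)),
                          center_times = ft, rate = 16000L),
                     class = "b2s_units")
  unit_database(fake_features(feature_matrix, ft), units)
}

# Speech-like test waveform: amplitude-modulated tones with pauses.
speechy_wave <- function(duration = 4, rate = 16000, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)[-1]
  env <- pmax(0, sin(2 * pi * 1.5 * t))^2 * (0.4 + 0.2 * sin(2 * pi * 0.4 * t))
  f <- 160 + 60 * sin(2 * pi * 0.7 * t)
  x <- env * (sin(2 * pi * cumsum(f) / rate) +
              0.6 * sin(2 * pi * cumsum(4 * f) / rate))
  x + rnorm(length(x), sd = 1e-4)
}

# Exhaustive double-loop cosine argmax, the independent selection oracle.
brute_force_select <- function(test_m, train_m) {
  idx <- integer(nrow(test_m)); sim <- numeric(nrow(test_m))
  for (i in seq_len(nrow(test_m))) {
    best <- -Inf; bi <- 1L
    for (j in seq_len(nrow(train_m))) {
      s <- cosine_similarity(test_m[i, ], train_m[j, ])
      if (s > best + 1e-15) { best <- s; bi <- j }
    }
    idx[i] <- bi; sim[i] <- best
  }
  list(indices = idx, similarities = sim)
}
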