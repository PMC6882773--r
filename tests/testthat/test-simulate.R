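test_that("simulated sessions have the configured shapes and rates", {
  cfg <- sim_config(n_words = 4, n_channels = 64, seed = 2)
  s <- simulate_session(cfg)
  dur <- 4 * 2.0
  expect_equal(dim(s$neural), c(64L, dur * 2000))
  expect_length(s$audio, dur * 48000)
  expect_equal(s$neural_rate, 2000)
  expect_equal(s$audio_rate, 48000)
  expect_equal(nrow(s$words), 4L)
  expect_equal(unname(table(s$channels$region)[c("IFG", "PMv", "M1v", "OTHER")]),
               c(12L, 20L, 18L, 14L), ignore_attr = TRUE)
  # word pacing: one word per 2 s period, inside the recording
  expect_true(all(diff(s$words$onset) > 1.5 & diff(s$words$onset) < 2.5))
  expect_true(all(s$words$offset <= dur))
})

test_that("identical seeds give identical sessions; different seeds differ", {
  a <- simulate_session(sim_config(n_words = 2, n_channels = 4,
                                   region_plan = c(M1v = 4), seed = 7))
  b <- simulate_session(sim_config(n_words = 2, n_channels = 4,
                                   region_plan = c(M1v = 4), seed = 7))
  expect_identical(a$neural, b$neural)
  expect_identical(a$audio, b$audio)
  expect_identical(a$words, b$words)
  c <- simulate_session(sim_config(n_words = 2, n_channels = 4,
                                   region_plan = c(M1v = 4), seed = 8))
  expect_false(identical(a$neural, c$neural))
})

test_that("config validation catches inconsistent plans", {
  expect_error(sim_config(coupling = 1.5), "coupling")
  expect_error(sim_config(n_channels = 10,
                          region_plan = c(IFG = 4, M1v = 4)), "sum")
  expect_error(sim_config(n_words = 0), "n_words")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("word trajectories are deterministic, smooth, label-specific", {
  t1 <- word_trajectory("bat", 0.6, seed = 4)
  t2 <- word_trajectory("bat", 0.6, seed = 4)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(120L, 4L))
  # smooth: successive 5 ms differences stay small relative to range
  expect_lt(max(abs(diff(t1))), 0.12 * diff(range(t1)))
  # distinct labels draw distinct shapes
  t3 <- word_trajectory("dog", 0.6, seed = 4)
  expect_lt(abs(cor(t1[, 1], t3[, 1])), 0.999)
  # same label, different base seed -> different shape
  t4 <- word_trajectory("bat", 0.6, seed = 5)
  expect_false(identical(t1, t4))
})

test_that("repeated tokens of a word are acoustically similar", {
  s <- tiny_session()      # 3-label inventory, 6 tokens -> labels recur
  w <- s$words
  a16 <- resample_signal(s$audio, s$audio_rate, 16000)
  tok_mel <- function(i) {
    seg <- a16[round(w$onset[i] * 16000):round((w$onset[i] + 0.5) * 16000)]
    colMeans(mel_spectrogram(seg)$values)
  }
  lab <- w$label
  same <- c(); diff_ <- c()
  for (i in 1:(nrow(w) - 1)) for (j in (i + 1):nrow(w)) {
    r <- cor(tok_mel(i), tok_mel(j))
    if (lab[i] == lab[j]) same <- c(same, r) else diff_ <- c(diff_, r)
  }
  expect_gt(mean(same), mean(diff_))
})

test_that("coupling modulates the in-word high-gamma power variance", {
  # the latent readout multiplies the 70-170 Hz carrier amplitude, so at
  # coupling 1 the in-word log band power fluctuates more than in silence;
  # at coupling 0 word and silence frames are statistically alike
  excess_var <- function(coupling) {
    cfg <- sim_config(n_words = 4, n_channels = 2,
                      region_plan = c(M1v = 2),
                      word_inventory = c("bat", "dog"),
                      coupling = coupling, seed = 6)
    s <- simulate_session(cfg)
    bp <- preprocess_ecog(s$neural, s$neural_rate)
    ft <- usable_frames(session_duration(s), "centered")
    f <- extract_context_features(bp, ft, "centered")
    inword <- rep(FALSE, length(f$frame_times))
    for (i in seq_len(nrow(s$words)))
      inword[f$frame_times >= s$words$onset[i] &
             f$frame_times < s$words$offset[i]] <- TRUE
    stats::var(f$values[inword, 5]) - stats::var(f$values[!inword, 5])
  }
  expect_gt(excess_var(1), excess_var(0) + 0.01)
})
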