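test_that("mel spectrogram: 40 coefficients, log floor, tone localization", {
  m <- mel_spectrogram(speechy_wave(2))
  expect_equal(ncol(m$values), 40L)
  z <- mel_spectrogram(numeric(16000))
  expect_true(all(abs(z$values - log(1e-10)) < 1e-9))
  # 1 kHz tone peaks in the filter whose center is nearest 1 kHz
  t <- seq(0, 1, by = 1 / 16000)[-1]
  tone <- mel_spectrogram(0.5 * sin(2 * pi * 1000 * t))
  peak <- which.max(colMeans(tone$values))
  expect_equal(peak, which.min(abs(tone$centers - 1000)))
  expect_error(mel_spectrogram(numeric(100)), "window")
})

test_that("word correlations: identity, offset invariance, gain invariance", {
  aud <- speechy_wave(4)
  words <- data.frame(label = c("w1", "w2"), onset = c(0.4, 2.1),
                      offset = c(1.6, 3.4))
  r_id <- word_correlations(aud, aud, words)
  expect_true(all(abs(r_id$coef_r[!is.na(r_id$coef_r)] - 1) < 1e-9))
  expect_equal(r_id$grand_mean_r, 1, tolerance = 1e-9)
  # a global gain on the reconstruction shifts log-mel by a constant:
  # Pearson r is location invariant
  r_gain <- word_correlations(aud, 3.7 * aud, words)
  expect_equal(r_gain$grand_mean_r, r_id$grand_mean_r, tolerance = 1e-6)
  expect_error(word_correlations(aud, aud[-1], words), "length")
})

test_that("uncorrelated reconstruction gives near-zero grand mean r", {
  set.seed(14)
  n <- 12 * 16000
  orig <- stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2)
  orig[is.na(orig)] <- 0
  recon <- stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2)
  recon[is.na(recon)] <- 0
  words <- data.frame(label = "long", onset = 0.5, offset = 11.5)
  r <- word_correlations(as.numeric(orig), as.numeric(recon), words)
  expect_lt(abs(r$grand_mean_r), 0.1)
})

test_that("degenerate words: too few frames or zero variance handled", {
  aud <- speechy_wave(3)
  words <- data.frame(label = c("ok", "tiny"), onset = c(0.3, 2.0),
                      offset = c(1.8, 2.015))
  r <- word_correlations(aud, aud, words)
  expect_true(is.na(r$per_word$mean_r[2]))       # < 3 mel frames
  expect_false(is.na(r$per_word$mean_r[1]))
  # grand mean skips undefined words
  expect_equal(r$grand_mean_r, r$per_word$mean_r[1])
})

test_that("randomization baseline: cardinality, determinism, chance = max", {
  aud <- speechy_wave(3)
  ft <- usable_frames(3, "centered")
  u <- extract_units(aud, 16000, ft)
  db <- unit_database(fake_features(matrix(rnorm(length(ft) * 3),
                                           length(ft)), ft), u)
  words <- data.frame(label = "w", onset = 0.5, offset = 2.5)
  d1 <- randomization_baseline(db, ft, words, aud, n_reps = 5, seed = 9)
  expect_length(d1$values, 5)
  expect_equal(d1$chance_level, max(d1$values))
  d2 <- randomization_baseline(db, ft, words, aud, n_reps = 5, seed = 9)
  expect_identical(d1$values, d2$values)
  d3 <- randomization_baseline(db, ft, words, aud, n_reps = 5, seed = 10)
  expect_false(identical(d1$values, d3$values))
})

test_that("empirical significance tiers follow the order statistics", {
  dist <- (1:1000) / 1000
  # exceeds exactly 950 of 1000 but not 990
  expect_equal(empirical_significance(0.9505, dist), "95%")
  expect_equal(empirical_significance(0.9905, dist), "99%")
  expect_equal(empirical_significance(2, dist), "99.9%")      # above all
  expect_equal(empirical_significance(stats::median(dist), dist), "n.s.")
  # monotone: a larger observed value never lowers the tier
  set.seed(2)
  d <- rnorm(500)
  tiers <- c("n.s." = 0, "95%" = 1, "99%" = 2, "99.9%" = 3)
  obs <- sort(runif(20, min(d) - 1, max(d) + 1))
  lv <- tiers[vapply(obs, empirical_significance, "", dist = d)]
  expect_true(all(diff(lv) >= 0))
})

test_that("STOI logistic mapping reproduces its printed anchor pairs", {
  expect_equal(round(stoi_to_intelligibility(0.15), 2), 0.36)
  expect_equal(round(stoi_to_intelligibility(0.25), 2), 0.41)
  # inverse identity on (0, 1)
  for (d in c(0.1, 0.5, 0.9))
    expect_equal(stoi_to_intelligibility(intelligibility_to_stoi(d)), d,
                 tolerance = 1e-12)
  expect_equal(stoi_to_intelligibility(0), 0)
  expect_equal(stoi_to_intelligibility(1), 1)
})

test_that("STOI scores identity high, noise low, degradation monotone", {
  orig <- speechy_wave(4, seed = 1)
  expect_gt(compute_stoi(orig, orig), 0.95)
  set.seed(6)
  noise <- rnorm(length(orig), sd = sd(orig))
  # frozen from an independently written reference implementation of the
  # measure on this exact signal pair: 0.2403 (small slack covers the
  # different polyphase resamplers); the -15 dB clipping stage gives
  # unrelated noise a floor well above zero
  s_noise <- compute_stoi(orig, noise)
  expect_lt(abs(s_noise - 0.2403), 0.02)
  s1 <- compute_stoi(orig, orig + 0.5 * sd(orig) * rnorm(length(orig)))
  expect_gte(compute_stoi(orig, orig), s1)
  expect_gt(s1, s_noise)
  expect_error(compute_stoi(orig, orig[-1]), "length")
  expect_error(compute_stoi(orig[1:1000], orig[1:1000]), "segment")
})
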