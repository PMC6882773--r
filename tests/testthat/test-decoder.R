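test_that("cosine similarity behaves like the target-cost definition", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  # invariance to positive (gamma) scaling
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(cosine_similarity(c(1, 1), c(-1, -1)), -1.0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("select_units matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    nt <- sample(3:20, 1); ntr <- sample(5:30, 1); d <- sample(2:6, 1)
    test_m <- matrix(rnorm(nt * d), nt)
    train_m <- matrix(rnorm(ntr * d), ntr)
    db <- fake_db(train_m)
    got <- select_units(fake_features(test_m), db)
    want <- brute_force_select(test_m, train_m)
    expect_identical(got$indices, want$indices)
    expect_equal(got$similarities, want$similarities, tolerance = 1e-9)
  }
})

test_that("selection is invariant to positive scaling of a test vector", {
  set.seed(3)
  test_m <- matrix(rnorm(30), 6, 5)
  db <- fake_db(matrix(rnorm(100), 20, 5))
  base <- select_units(fake_features(test_m), db)$indices
  test_m[4, ] <- test_m[4, ] * 37.5
  expect_identical(select_units(fake_features(test_m), db)$indices, base)
})

test_that("selection is permutation-covariant over database rows", {
  set.seed(8)
  train_m <- matrix(rnorm(60), 12, 5)
  test_m <- matrix(rnorm(25), 5, 5)
  perm <- sample(12)
  i1 <- select_units(fake_features(test_m), fake_db(train_m))$indices
  i2 <- select_units(fake_features(test_m), fake_db(train_m[perm, ]))$indices
  expect_identical(perm[i2], i1)
})

test_that("degenerate cases: single-unit database, zero-norm frames, ties", {
  db1 <- fake_db(matrix(rnorm(4), 1, 4))
  sel <- select_units(fake_features(matrix(rnorm(12), 3, 4)), db1)
  expect_identical(sel$indices, rep(1L, 3))
  # zero-norm test frame: all similarities 0 -> first unit
  m <- rbind(c(0, 0), c(1, 1))
  sel0 <- select_units(fake_features(m), fake_db(matrix(c(1, 0, 1, 2), 2)))
  expect_equal(sel0$indices[1], 1L)
  expect_equal(sel0$similarities[1], 0)
  # exact ties break to the lowest training index
  tied <- fake_db(rbind(c(2, 0), c(1, 0), c(4, 0)))
  selt <- select_units(fake_features(matrix(c(3, 0), 1)), tied)
  expect_equal(selt$indices, 1L)
  expect_error(select_units(fake_features(matrix(1, 1, 3)), db1), "dimension")
})

test_that("self-decoding selects each frame's own unit with similarity 1", {
  set.seed(11)
  m <- matrix(rnorm(40 * 6), 40)
  db <- fake_db(m)
  sel <- select_units(fake_features(m), db)
  expect_identical(sel$indices, 1:40)
  expect_true(all(abs(sel$similarities - 1) < 1e-9))
})

test_that("blocked search equals single-block search", {
  set.seed(21)
  test_m <- matrix(rnorm(50 * 4), 50)
  db <- fake_db(matrix(rnorm(30 * 4), 30))
  a <- select_units(fake_features(test_m), db, block = 7L)
  b <- select_units(fake_features(test_m), db)
  expect_identical(a$indices, b$indices)
  expect_equal(a$similarities, b$similarities)
})

test_that("decode_session restricts to the model's channel subset", {
  s <- tiny_session()
  m <- fit_decoder_model(s, regions = "M1v", pca_threshold = 0.7)
  # feature space before PCA: |M1v| channels x 9 bins
  expect_equal(m$normalizer$n_features,
               sum(s$channels$region == "M1v") * 9)
  out <- decode_session(s, m)
  expect_equal(length(out$waveform),
               round(session_duration(s) * 16000))
  expect_true(all(abs(out$selection$similarities - 1) < 1e-9))  # self-match
  expect_error(fit_decoder_model(s, regions = character(0)), "empty|region")
  s2 <- s
  s2$channels$name <- rev(s2$channels$name)
  expect_error(decode_session(s2, m), "channel")
})
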