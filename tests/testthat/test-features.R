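test_that("context windows yield 9 bins per channel, channel-major", {
  bp <- fake_bandpower(3, duration = 4, seed = 2)
  f <- extract_context_features(bp, usable_frames(4, "centered"), "centered")
  expect_equal(ncol(f$values), 3 * 9)
  expect_equal(f$bins, 9L)
  # layout bijection: unflattening recovers the channels x 9 matrix
  v <- f$values[10, ]
  m <- unflatten_features(v, 3)
  expect_equal(m[2, ], v[10:18])
  expect_equal(as.vector(t(m)), v)
})

test_that("constant power gives constant bin values before normalization", {
  bp <- fake_bandpower(2, duration = 3)
  bp$values[] <- 1.7
  f <- extract_context_features(bp, usable_frames(3, "centered"), "centered")
  expect_true(all(abs(f$values - 1.7) < 1e-12))
})

test_that("frames crossing the recording boundary are dropped", {
  bp <- fake_bandpower(1, duration = 2)
  f <- extract_context_features(bp, frame_grid(2), "centered")
  expect_true(all(f$frame_times >= 0.225 - 1e-9))
  expect_true(all(f$frame_times <= 2 - 0.225 + 1e-9))
  f0 <- extract_context_features(bp, numeric(0), "centered")
  expect_equal(nrow(f0$values), 0L)
})

test_that("centered and causal modes use their stated windows", {
  bp <- fake_bandpower(1, duration = 6, seed = 4)
  t0 <- 3.0
  i0 <- round(t0 * 600) + 1
  fc <- extract_context_features(bp, t0, "causal")
  # causal: perturbing any sample after t leaves the feature unchanged
  bp2 <- bp
  bp2$values[, (i0 + 1):ncol(bp2$values)] <- 99
  fc2 <- extract_context_features(bp2, t0, "causal")
  expect_identical(fc$values, fc2$values)
  # and the window reaches exactly 450 ms back
  bp3 <- bp
  bp3$values[, 1:(i0 - 270)] <- -99
  expect_identical(extract_context_features(bp3, t0, "causal")$values,
                   fc$values)
  bp4 <- bp
  bp4$values[, i0 - 269] <- 50        # inside the causal window
  expect_false(identical(extract_context_features(bp4, t0, "causal")$values,
                         fc$values))
  # centered mode does look ahead
  fcen <- extract_context_features(bp, t0, "centered")
  fcen2 <- extract_context_features(bp2, t0, "centered")
  expect_false(identical(fcen$values, fcen2$values))
})

test_that("normalizer zero-means and unit-scales its training data only", {
  bp <- fake_bandpower(2, duration = 5, seed = 7)
  f <- extract_context_features(bp, usable_frames(5, "centered"), "centered")
  half <- seq_len(nrow(f$values) %/% 2)
  trn <- f; trn$values <- f$values[half, ]; trn$frame_times <- f$frame_times[half]
  nm <- fit_normalizer(trn)
  z <- apply_normalizer(trn, nm)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_equal(apply(z$values, 2, sd), rep(1, ncol(z$values)),
               ignore_attr = TRUE, tolerance = 1e-9)
  # test frames transformed with training statistics are not re-centered
  tst <- f; tst$values <- f$values[-half, , drop = FALSE]
  zt <- apply_normalizer(tst, nm)
  expect_gt(max(abs(colMeans(zt$values))), 1e-3)
})

test_that("constant (sd = 0) feature columns normalize to zero", {
  m <- cbind(rnorm(20), rep(3, 20))
  f <- fake_features(m)
  nm <- fit_normalizer(f)
  z <- apply_normalizer(f, nm)
  expect_true(all(z$values[, 2] == 0))
  bad <- fake_features(m[, 1, drop = FALSE])
  expect_error(apply_normalizer(bad, nm), "layout")
})

test_that("PCA keeps the smallest k reaching the variance threshold", {
  # exactly isotropic 10-d data: every component explains 1/10,
  # so threshold 0.70 needs k = 7
  set.seed(42)
  x <- matrix(rnorm(400), 40, 10)
  sv <- svd(x)
  iso <- sv$u %*% t(sv$v) * sqrt(40)
  p <- fit_pca(fake_features(iso), threshold = 0.70)
  expect_equal(ncol(p$components), 7L)
  # all variance on one axis -> k = 1
  one <- cbind(rnorm(30), 0, 0)
  p1 <- fit_pca(fake_features(one))
  expect_equal(ncol(p1$components), 1L)
  expect_equal(p1$threshold, 0.70)
})

test_that("PCA components are orthonormal and preserve >= 70% variance", {
  set.seed(9)
  x <- matrix(rnorm(200 * 12), 200) %*% diag(c(6:1, rep(0.3, 6)))
  f <- fake_features(x)
  p <- fit_pca(f, 0.70)
  expect_equal(crossprod(p$components),
               diag(ncol(p$components)), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_gte(sum(p$explained), 0.70)
  # back-projection loses at most 30% of total variance
  pr <- project_features(f, p)
  back <- pr$values %*% t(p$components)
  resid <- sweep(x, 2, p$mean) - back
  expect_lte(sum(apply(resid, 2, stats::var)) / sum(apply(x, 2, stats::var)),
             0.30 + 1e-9)
})
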