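test_that("signal matrix segmentation follows the [L(1..M), R(1..M)] layout", {
  sm <- build_signal_matrix(1:20, 1:20, M = 2, fs = 10)
  expect_equal(sm$N, 10L)
  expect_equal(sm$Q, 4L)
  expect_equal(sm$D[, 1], 1:10)
  expect_equal(sm$D[, 3], 1:10)  # right block restarts at the series head
  expect_equal(sm$side, c("L", "L", "R", "R"))
  expect_equal(sm$pair_index, c(1L, 2L, 1L, 2L))

  # N given: floor division discards the trailing remainder
  sm2 <- build_signal_matrix(seq_len(205), seq_len(205), N = 50, fs = 10)
  expect_equal(sm2$M, 4L)
  expect_equal(sm2$D[50, 4], 200)

  # M = 10 on 60 s at 100 Hz
  x <- rnorm(6000)
  sm3 <- build_signal_matrix(x, x, M = 10, fs = 100)
  expect_equal(sm3$N, 600L)
  expect_equal(sm3$Q, 20L)

  expect_error(build_signal_matrix(1:30, 1:30, M = 2, N = 15, fs = 10), "exactly one")
  expect_error(build_signal_matrix(1:10, 1:10, N = 50, fs = 10), "shorter")
  expect_warning(build_signal_matrix(1:100, 1:30, M = 2, fs = 10), "differ")
})

test_that("column DFT removes the mean and matches closed forms", {
  n_len <- 64
  sm <- build_signal_matrix(rep(3.7, n_len), cos(2 * pi * 5 * (0:(n_len - 1)) / n_len),
                            M = 1, fs = n_len)
  spec <- dft_columns(sm)
  # constant column: all coefficients vanish after mean removal
  expect_lt(max(abs(spec$G[, 1])), 1e-10)
  # cosine at bin m: energy split between bins m and N - m, magnitude N/2
  mag <- abs(spec$G[, 2])
  expect_equal(mag[5 + 1], n_len / 2, tolerance = 1e-9)
  expect_equal(mag[n_len - 5 + 1], n_len / 2, tolerance = 1e-9)
  expect_lt(max(mag[-c(6, n_len - 4)]), 1e-9)
  expect_equal(spec$resolution, 1)
})

test_that("fast transform agrees with the naive DFT and Parseval holds", {
  set.seed(11)
  for (n_len in c(8, 37, 64)) {
    x <- rnorm(n_len)
    sm <- build_signal_matrix(x, rnorm(n_len), M = 1, fs = 100)
    spec <- dft_columns(sm)
    for (col in 1:2) {
      oracle <- naive_dft(sm$D[, col])
      expect_lt(max(abs(spec$G[, col] - oracle)) / max(abs(oracle)), 1e-9)
      # Parseval: sum |g|^2 = N * sum (d - mean)^2
      lhs <- sum(abs(spec$G[, col])^2)
      rhs <- n_len * sum((sm$D[, col] - mean(sm$D[, col]))^2)
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("relative band power matches two-line spectra and normalization", {
  fs <- 100
  t <- (0:999) / fs
  pure <- sin(2 * pi * 1 * t)
  mix <- sin(2 * pi * 1 * t) + sin(2 * pi * 5 * t)
  sm <- build_signal_matrix(pure, mix, M = 1, fs = fs)
  spec <- dft_columns(sm)
  e_band <- band_power(spec, c(0.5, 3))
  expect_equal(e_band[1], 1, tolerance = 1e-9)   # single in-band line
  expect_equal(e_band[2], 0.5, tolerance = 1e-9) # equal split across the edge
  # full half-spectrum band normalizes to 1 for any non-constant column
  expect_equal(band_power(spec, c(fs / 1000, fs / 2)), c(1, 1), tolerance = 1e-12)
  expect_error(band_power(spec, c(3, 60)), "band")
  # constant column: zero total power reported as 0 with a warning
  smc <- build_signal_matrix(rep(1, 100), pure[1:100], M = 1, fs = fs)
  expect_warning(e0 <- band_power(dft_columns(smc), c(0.5, 3)), "constant")
  expect_equal(e0[1], 0)
})

test_that("pattern and target matrices have the documented layout", {
  left <- rep(2, 40)
  right <- c(rep(1, 20), rep(3, 20))
  sm <- build_signal_matrix(left, right, M = 2, fs = 10)
  fset <- build_feature_set(sm, features = "mean")
  expect_equal(unname(fset$P[1, 1:2]), c(2, 2))
  expect_equal(unname(fset$P[1, 3:4]), c(1, 3))
  expect_equal(unname(fset$T[1, ]), c(1, 1, 0, 0))
  expect_equal(unname(fset$T[2, ]), c(0, 0, 1, 1))
  expect_equal(colSums(fset$T), rep(1, 4), ignore_attr = TRUE)

  expect_warning(
    two <- build_feature_set(sm, features = c("std", "bandpower"),
                             bands = list(c(0.5, 3))),
    "constant")  # piecewise-constant fixture columns have no spectral power
  expect_equal(nrow(two$P), 2L)
  expect_error(build_feature_set(sm, features = character(0)), "features")
  expect_error(build_feature_set(sm, features = "kurtosis"), "kurtosis")
})

test_that("band powers are scale invariant and std scales linearly", {
  fset <- synth_fs(asym_amp = 0, noise_sd = 0.1, seed = 3, M = 5)
  pair <- generate_pair(synth_config(noise_sd = 0.1, seed = 3))
  scaled <- pair$L
  scaled$a <- scaled$a * 4
  sm <- build_signal_matrix(pair$L, scaled, M = 5)
  f2 <- build_feature_set(sm)
  bp_rows <- grep("^bandpower", f2$feature_names)
  expect_equal(f2$P[bp_rows, 1:5], f2$P[bp_rows, 6:10], tolerance = 1e-9)
  expect_equal(unname(f2$P["std", 6:10] / f2$P["std", 1:5]), rep(4, 5),
               tolerance = 1e-9)
  expect_equal(ncol(fset$P), 10L)  # column count conserved through FeatureSet
})

test_that("feature sets round-trip through CSV and JSON", {
  fset <- synth_fs(asym_amp = 0.2, noise_sd = 0.1, seed = 6, M = 4)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_feature_set(fset, path)
    back <- read_feature_set(path)
    # CSV stores %.17g and is bit-exact; JSON is near machine precision
    if (ext == ".csv") expect_equal(back$P, fset$P, tolerance = 0)
    else expect_equal(back$P, fset$P, tolerance = 1e-12)
    expect_identical(back$side, fset$side)
    expect_equal(back$T, fset$T, ignore_attr = TRUE)
  }
})
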