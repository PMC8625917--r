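# stationary wavelet transform core

test_that("constant and impulse signals decompose as the filters dictate", {
  co <- swt_decompose(rep(3.7, 512), wavelet_config(levels = 3))
  expect_true(all(vapply(co$details, function(d) max(abs(d)), numeric(1)) < 1e-10))
  # low-pass gain sqrt(2) per level: cA_3 = 3.7 * 2^(3/2)
  expect_equal(co$approximation, rep(3.7 * 2^1.5, 512), tolerance = 1e-12)

  # unit impulse: cD_1 must equal the direct circular correlation with
  # the db8 high-pass filter (independent oracle, computed here)
  x <- numeric(512); x[257] <- 1
  g <- wavelet_filters("db8")$g
  oracle <- numeric(512)
  for (k in seq_along(g)) oracle[((257 - 1 - (k - 1)) %% 512) + 1] <- g[k]
  co1 <- swt_decompose(x, wavelet_config(levels = 1))
  expect_equal(co1$details[[1]], oracle, tolerance = 1e-14)
})

test_that("round trip is perfect for random signals, all depths, both boundary modes", {
  set.seed(42)
  for (mode in c("periodic", "symmetric")) {
    for (k in c(1, 3, 5)) {
      x <- rnorm(1024)
      co <- swt_decompose(x, wavelet_config(levels = k, boundary = mode))
      expect_lt(max(abs(swt_reconstruct(co) - x)), 1e-8 * max(abs(x)))
    }
  }
  # n not a power of two
  x <- rnorm(1000)
  co <- swt_decompose(x, wavelet_config(levels = 5))
  expect_lt(max(abs(swt_reconstruct(co) - x)), 1e-8)
})

test_that("transform is linear and (periodic mode) exactly shift invariant", {
  set.seed(7)
  x <- rnorm(512); y <- rnorm(512)
  cfg <- wavelet_config(levels = 4)
  cxy <- swt_decompose(2 * x - 3 * y, cfg)
  cx <- swt_decompose(x, cfg); cy <- swt_decompose(y, cfg)
  for (j in 1:4) {
    expect_equal(cxy$details[[j]], 2 * cx$details[[j]] - 3 * cy$details[[j]],
                 tolerance = 1e-10)
  }
  expect_equal(cxy$approximation, 2 * cx$approximation - 3 * cy$approximation,
               tolerance = 1e-10)

  m <- 97
  xs <- c(x[(m + 1):512], x[1:m])
  cs <- swt_decompose(xs, cfg)
  for (j in 1:4) {
    shifted <- c(cx$details[[j]][(m + 1):512], cx$details[[j]][1:m])
    expect_lt(max(abs(cs$details[[j]] - shifted)), 1e-8)
  }
})

test_that("reconstruction is linear in the coefficients", {
  set.seed(11)
  x <- rnorm(256)
  co <- swt_decompose(x, wavelet_config(levels = 3))
  only_a <- co; for (j in 1:3) only_a$details[[j]][] <- 0
  only_d <- co; only_d$approximation[] <- 0
  expect_equal(swt_reconstruct(only_a) + swt_reconstruct(only_d), x,
               tolerance = 1e-8)
  zero <- co
  for (j in 1:3) zero$details[[j]][] <- 0
  zero$approximation[] <- 0
  expect_equal(swt_reconstruct(zero), numeric(256))
})

test_that("invalid inputs raise the documented errors", {
  expect_error(swt_decompose(rnorm(16), wavelet_config(levels = 5)),
               "too short")
  expect_error(swt_decompose(c(rnorm(511), NA), wavelet_config(levels = 2)),
               "finite")
  co <- swt_decompose(rnorm(64), wavelet_config(levels = 2))
  co$details[[1]] <- co$details[[1]][-1]
  expect_error(swt_reconstruct(co), "length")
})

test_that("energy shares sum to 100, are scale invariant, and land in the right band", {
  fs <- 250
  t <- (0:1023) / fs
  x <- sin(2 * pi * 30 * t)
  co <- swt_decompose(x, wavelet_config(levels = 3))
  ed <- energy_distribution(co, fs)
  expect_equal(sum(ed$energy_pct), 100, tolerance = 1e-9)
  expect_true(all(ed$energy_pct >= 0))
  # 30 Hz lies in the d3 band [15.625, 31.25]
  expect_identical(ed$level[which.max(ed$energy_pct)], "d3")
  expect_equal(ed$f_low[ed$level == "d3"], 15.625)
  # scaling the signal leaves the shares untouched
  ed2 <- energy_distribution(swt_decompose(7 * x, wavelet_config(levels = 3)), fs)
  expect_equal(ed2$energy_pct, ed$energy_pct, tolerance = 1e-9)
  # fs = 500, k = 5: approximation/d5 boundary at 7.8125 Hz, d5 top edge
  # 15.625 Hz (the band holding the QRS spectral peak)
  ed5 <- energy_distribution(
    swt_decompose(rnorm(256), wavelet_config(levels = 5)), 500)
  expect_equal(ed5$f_high[ed5$level == "a5"], 7.8125)
  expect_equal(ed5$f_low[ed5$level == "d5"], 7.8125)
  expect_equal(ed5$f_high[ed5$level == "d5"], 15.625)
  # zero-energy input is a degenerate case, not a silent NaN
  z <- swt_decompose(numeric(64), wavelet_config(levels = 2))
  expect_error(energy_distribution(z, fs), "zero-energy")
})
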