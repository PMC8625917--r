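# baseline removal and adaptive denoising

test_that("baseline removal conserves the signal and kills sub-Hz drift", {
  z <- remove_baseline(numeric(64))
  expect_equal(z$corrected, numeric(64))
  expect_equal(z$baseline, numeric(64))

  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  drift <- sin(2 * pi * 0.2 * t)
  out <- remove_baseline(drift, fs)
  expect_equal(out$corrected + out$baseline, drift)  # exact conservation
  expect_lt(sqrt(mean(out$corrected^2)), 0.05 * sqrt(mean(drift^2)))
})

test_that("drift under a synthetic ECG is removed without flattening the R peaks", {
  g <- generate_ecg(clean_spec(duration_s = 20, seed = 3))
  fs <- g$signal$fs
  n <- length(g$signal$samples)
  t <- (seq_len(n) - 1) / fs
  drift <- seq(-0.5, 0.5, length.out = n) + 0.3 * sin(2 * pi * 0.15 * t)
  noisy <- g$signal$samples + drift
  out <- remove_baseline(noisy, fs)

  # band power below 0.5 Hz via the FFT (independent spectral oracle)
  band_power <- function(x, f_hi) {
    f <- (seq_len(n) - 1) / n * fs
    keep <- (f > 0 & f < f_hi) | (f > fs - f_hi)
    sum(Mod(stats::fft(x))[keep]^2)
  }
  expect_lt(band_power(out$corrected, 0.5), 0.1 * band_power(noisy, 0.5))

  # R-peak amplitudes preserved within 10%
  idx <- round(g$truth$peak_times * fs) + 1
  expect_lt(max(abs(out$corrected[idx] - g$signal$samples[idx])), 0.1)
})

test_that("baseline removal is idempotent to first order", {
  g <- generate_ecg(clean_spec(duration_s = 20, seed = 7, baseline_mv = 0.2,
                               baseline_hz = 0.3))
  o1 <- remove_baseline(g$signal$samples, g$signal$fs)
  o2 <- remove_baseline(o1$corrected, g$signal$fs)
  expect_lt(sqrt(mean((o2$corrected - o1$corrected)^2)),
            0.01 * sqrt(mean(o1$corrected^2)))
})

test_that("level threshold equals the dispersion formula and is consistent", {
  expect_equal(level_threshold(c(5, 5, 5, 5)), 0)
  expect_equal(level_threshold(c(0, 2, 0, 2)), 2 / sqrt(3), tolerance = 1e-12)
  # brute-force oracle on random coefficients
  set.seed(9)
  for (i in 1:5) {
    cd <- rnorm(101, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    expect_equal(level_threshold(cd),
                 sqrt(sum((cd - mean(cd))^2) / (length(cd) - 1)),
                 tolerance = 1e-12)
  }
  # Monte-Carlo: for iid N(0, sigma) the threshold estimates sigma
  set.seed(10)
  cd <- rnorm(1e5, sd = 0.7)
  expect_equal(level_threshold(cd), 0.7, tolerance = 0.02 * 0.7)
  expect_error(level_threshold(3), "at least 2")
})

test_that("soft threshold obeys its scalar contract", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(c(-0.2, 0, 1.5), 0.5), c(0, 0, 1))
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("denoising is scale covariant, contractive, and near-transparent on clean tones", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y <- denoise(x, wavelet_config(levels = 5))
  expect_lt(sqrt(mean((y - x)^2)), 0.1 * sqrt(mean(x^2)))

  set.seed(21)
  z <- rnorm(512)
  expect_equal(denoise(3.5 * z), 3.5 * denoise(z), tolerance = 1e-9)
  expect_lte(sum(denoise(z)^2), sum(z^2))
})

test_that("snr_improvement matches its closed-form definition", {
  set.seed(2)
  clean <- sin(2 * pi * 5 * (0:999) / 250)
  noisy <- clean + rnorm(1000, sd = 0.3)
  expect_equal(snr_improvement(noisy, noisy, clean), 0)
  # halving residual noise power gives exactly 10*log10(2) dB
  halved <- clean + (noisy - clean) / sqrt(2)
  expect_equal(snr_improvement(noisy, halved, clean), 10 * log10(2),
               tolerance = 1e-9)
  # processed == clean is capped, not infinite
  expect_true(is.finite(snr_improvement(noisy, clean, clean)))
  expect_error(snr_improvement(noisy, halved, clean[-1]), "equal lengths")
})

test_that("denoising white-noise-corrupted ECG improves the SNR", {
  # shrinkage alone, white noise only, at the 0 and 5 dB input SNRs
  # where detail energy is noise dominated
  for (seed in 1:3) {
    for (snr_in_db in c(0, 5)) {
      g <- generate_ecg(clean_spec(duration_s = 8, seed = seed))
      clean <- g$signal$samples
      sigma <- sqrt(mean(clean^2) / 10^(snr_in_db / 10))
      set.seed(1000 + seed)
      noisy <- clean + rnorm(length(clean), sd = sigma)
      den <- denoise(noisy, wavelet_config(levels = 5))
      expect_gt(snr_improvement(noisy, den, clean), 0)
    }
  }
})

test_that("the full preprocessing chain improves SNR across the 0-10 dB range", {
  # realistic corruption: baseline wander + mains pickup + white noise;
  # improvement measured against the clean beat train
  improvements <- c()
  for (seed in 1:4) {
    for (snr_in_db in c(0, 5, 10)) {
      clean <- generate_ecg(clean_spec(duration_s = 8, seed = seed))$signal$samples
      noisy_g <- generate_ecg(clean_spec(duration_s = 8, seed = seed,
                                         baseline_mv = 0.3, baseline_hz = 0.3,
                                         powerline_mv = 0.1, powerline_hz = 50))
      sigma <- sqrt(mean(clean^2) / 10^(snr_in_db / 10))
      set.seed(2000 + seed)
      noisy <- noisy_g$signal$samples + rnorm(length(clean), sd = sigma)
      den <- denoise(remove_baseline(noisy, 250)$corrected,
                     wavelet_config(levels = 5))
      improvements <- c(improvements, snr_improvement(noisy, den, clean))
    }
  }
  expect_true(all(improvements > 0))
  # the improvements sit in a plausible clinical range (single dB digits)
  expect_gt(max(improvements), 1.3)
  expect_lt(max(improvements), 15)
})
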