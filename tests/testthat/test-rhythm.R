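# R-peak detection, RR analysis, alarms, HRV

test_that("all ground-truth peaks of a clean record are recovered, none invented", {
  g <- generate_ecg(clean_spec(duration_s = 10, seed = 2))
  det <- detect_r_peaks(g$signal)
  truth <- truth_after_warmup(g$truth)
  sc <- score_detection(det$peaks$time_s, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$ppv, 1)
  # every reported peak is after the warm-up
  expect_true(all(det$peaks$time_s >= 2))
  # spacing respects the refractory period
  expect_true(all(diff(det$peaks$time_s) >= 0.2))
})

test_that("the 70% amplitude rule and warm-up are enforced", {
  fs <- 250
  # hand-built signal: reference-setting spike of 1.0 at t = 3 s, a
  # 0.65 candidate at t = 5 s (rejected), a 0.8 candidate at 7 s (kept)
  x <- numeric(10 * fs)
  spike <- function(t0, a) x[round(t0 * fs) + 1] <<- a
  spike(0.5, 0.9)   # inside warm-up: may set amplitude but never a peak
  spike(3, 1.0)
  spike(5, 0.65)
  spike(7, 0.8)
  det <- detect_r_peaks(x, fs)
  expect_equal(det$reference, 1.0)
  expect_true(all(det$peaks$time_s >= 2))
  expect_false(any(abs(det$peaks$time_s - 5) < 0.01))  # 0.65 < 0.7 * 1.0
  expect_true(any(abs(det$peaks$time_s - 7) < 0.01))
})

test_that("flat or empty input yields an empty peak train, bad fs errors", {
  det <- detect_r_peaks(numeric(2500), 250)
  expect_equal(nrow(det$peaks), 0)
  expect_error(detect_r_peaks(rnorm(100), -1), "fs")
})

test_that("shifting the signal shifts the detected peaks (after warm-up)", {
  g <- generate_ecg(clean_spec(duration_s = 10, seed = 4))
  fs <- g$signal$fs
  m <- 50
  shifted <- c(numeric(m), g$signal$samples)
  d0 <- detect_r_peaks(g$signal$samples, fs)
  d1 <- detect_r_peaks(shifted, fs)
  t0 <- d0$peaks$time_s[d0$peaks$time_s >= 2.5]
  t1 <- d1$peaks$time_s[d1$peaks$time_s >= 2.5 + m / fs]
  expect_equal(t1, t0 + m / fs, tolerance = 1e-12)
})

test_that("rr intervals and relative RR follow their definitions", {
  rr <- rr_intervals(data.frame(time_s = c(0, 125, 250) / 250))
  expect_equal(rr$rr_s, c(0.5, 0.5))
  expect_equal(rr$rel_rr, c(NA, 0))

  rr2 <- rr_intervals(c(0, 0.5, 1.1))
  expect_equal(rr2$rel_rr[2], 2 * (0.6 - 0.5) / (0.6 + 0.5), tolerance = 1e-12)

  # algebraic bound and antisymmetry under interval swap
  set.seed(5)
  a <- runif(50, 0.2, 2); b <- runif(50, 0.2, 2)
  rel <- 2 * (b - a) / (a + b)
  expect_true(all(abs(rel) < 2))
  expect_equal(2 * (a - b) / (b + a), -rel)

  expect_equal(nrow(rr_intervals(c(1))), 0)
})

test_that("bradycardia and tachycardia rules fire as specified", {
  mk <- function(rr) {
    out <- data.frame(rr_s = rr,
                      rel_rr = c(NA, 2 * diff(rr) / (rr[-length(rr)] + rr[-1])),
                      end_time_s = cumsum(rr))
    class(out) <- c("rr_series", "data.frame")
    out
  }
  r <- classify_rhythm(mk(c(0.45, 0.67, 0.50)))
  expect_equal(nrow(r$events), 1)
  expect_equal(r$events$kind, "bradycardia")
  expect_equal(r$events$rr_values_s[[1]], 0.67)

  # strict inequality at the boundary
  expect_equal(nrow(classify_rhythm(mk(c(0.6, 0.6)))$events), 0)

  # one alarm per maximal run, all triggering values stored
  r2 <- classify_rhythm(mk(c(0.5, 0.65, 0.7, 0.5, 0.62, 0.5)))
  br <- r2$events[r2$events$kind == "bradycardia", ]
  expect_equal(nrow(br), 2)
  expect_equal(br$rr_values_s[[1]], c(0.65, 0.7))

  # tachycardia needs two consecutive short intervals
  expect_equal(nrow(classify_rhythm(mk(c(0.40, 0.5, 0.40)))$events), 0)
  r3 <- classify_rhythm(mk(c(0.40, 0.41, 0.5)))
  expect_equal(r3$events$kind, "tachycardia")
  expect_equal(r3$events$rr_values_s[[1]], c(0.40, 0.41))

  # two-beat confirmation mode for bradycardia
  expect_equal(nrow(classify_rhythm(mk(c(0.45, 0.67, 0.50)),
                                    brady_min_beats = 2)$events), 0)
  expect_equal(nrow(classify_rhythm(mk(c(0.45, 0.67, 0.66)),
                                    brady_min_beats = 2)$events), 1)

  # irregularity flags on |relative RR| > 0.2
  r4 <- classify_rhythm(mk(c(0.5, 0.5, 0.7)))
  expect_equal(r4$irregular, c(NA, FALSE, TRUE))
})

test_that("every injected bradycardia episode raises exactly one alarm; normal rhythm raises none", {
  for (seed in 1:3) {
    g <- generate_ecg(synth_spec(
      fs = 250, duration_s = 60, base_hr_bpm = 130, seed = seed,
      brady_episodes = data.frame(start_s = c(15, 40),
                                  n_beats = c(3, 2),
                                  rr_s = c(0.7, 0.8))))
    res <- process_stream(g$signal, config = pipeline_config())
    br <- res$alarms[res$alarms$kind == "bradycardia", ]
    expect_equal(nrow(br), 2)
    # alarms land inside the injected episodes
    for (i in 1:2) {
      expect_true(any(br$onset_time_s >= g$truth$brady_intervals$start_s[i] &
                        br$onset_time_s <= g$truth$brady_intervals$end_s[i] + 0.1))
    }
  }
  # normal sinus rhythm, rr uniform in [0.35, 0.55]: no bradycardia alarm
  set.seed(77)
  rr <- runif(200, 0.35, 0.55)
  cls <- classify_rhythm(rr_intervals(cumsum(c(0, rr))))
  expect_equal(sum(cls$events$kind == "bradycardia"), 0)
})

test_that("HRV metrics equal their brute-force formulas", {
  h <- hrv_metrics(c(0.67, 0.68, 0.67))
  expect_equal(h$rmssd_ms, 10, tolerance = 1e-9)

  expect_equal(hrv_metrics(rep(0.5, 20))$rmssd_ms, 0)
  expect_equal(hrv_metrics(rep(0.5, 20))$sdnn_ms, 0)

  set.seed(31)
  rr <- runif(500, 0.3, 0.9)
  h2 <- hrv_metrics(rr, sdann_window_s = 5)
  expect_equal(h2$rmssd_ms, sqrt(mean(diff(rr)^2)) * 1000, tolerance = 1e-9)
  expect_equal(h2$sdnn_ms, sd(rr) * 1000, tolerance = 1e-9)
  # SDANN brute force: mean rr per 5 s window of interval end times
  endt <- cumsum(rr)
  mw <- tapply(rr, floor(endt / 5), mean)
  expect_equal(h2$sdann_ms, sd(mw) * 1000, tolerance = 1e-9)

  # undefined, not zero, when preconditions fail
  h3 <- hrv_metrics(c(0.5))
  expect_true(is.na(h3$rmssd_ms) && is.na(h3$sdnn_ms) && is.na(h3$sdann_ms))
})

test_that("detection survives 10 dB input SNR after preprocessing", {
  hits <- 0; total <- 0; fp <- 0
  for (seed in 1:3) {
    g <- generate_ecg(clean_spec(duration_s = 20, seed = seed))
    clean <- g$signal$samples
    sigma <- sqrt(mean(clean^2) / 10)  # 10 dB input SNR
    set.seed(400 + seed)
    g$signal$samples <- clean + rnorm(length(clean), sd = sigma)
    res <- process_stream(g$signal, config = pipeline_config())
    truth <- truth_after_warmup(g$truth)
    sc <- score_detection(res$peaks$time_s, truth, tol_s = 0.02)
    hits <- hits + sc$n_matched
    total <- total + length(truth)
    fp <- fp + (nrow(res$peaks) - sc$n_matched)
  }
  expect_gte(hits / total, 0.95)
  expect_gte(hits / (hits + fp), 0.95)
})
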