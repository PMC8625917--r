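# Block-streaming orchestration: buffer the incoming samples into
# fixed-size blocks (default 1000, i.e. 4 s at 250 Hz / 2 s at 500 Hz:
# one block is processed while the next is stored), and per block run
# baseline removal -> denoising -> R-peak detection -> RR/alarms ->
# optional compression. Detector and rhythm-classifier state are
# carried across block boundaries, so results are identical no matter
# how the input is chunked before being fed in.

#' Pipeline configuration
#'
#' @param block_size Samples per processing block (default 1000).
#' @param wavelet,levels,boundary Wavelet settings, see
#'   [wavelet_config()].
#' @param peak_fraction Amplitude acceptance fraction of the reference
#'   peak (default 0.7).
#' @param brady_threshold_s,tachy_threshold_s RR alarm bounds in
#'   seconds (defaults 0.6 and 0.43: rates of 100 and 140 bpm).
#' @param relative_band Irregularity band on the relative RR (default
#'   0.20).
#' @param brady_min_beats Beats required for a bradycardia alarm
#'   (default 1; 2 gives the stricter clinical rule).
#' @param warmup_s Detector warm-up (default 2 s).
#' @param refractory_s Detector refractory period (default 0.2 s).
#' @param hrv_window_s HRV reporting window in seconds (default 5; 2
#'   is the other recommended short window).
#' @param compress Compress each raw block (default `FALSE`).
#' @param bits Quantizer bits when compressing (default 8).
#' @param invert Negate the signal for inverted leads.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(block_size = 1000L, wavelet = "db8", levels = 5L,
                            boundary = "periodic", peak_fraction = 0.7,
                            brady_threshold_s = 0.6, tachy_threshold_s = 0.43,
                            relative_band = 0.20, brady_min_beats = 1L,
                            warmup_s = 2, refractory_s = 0.2,
                            hrv_window_s = 5, compress = FALSE, bits = 8L,
                            invert = FALSE) {
  block_size <- as.integer(block_size)
  if (block_size < 2L^levels) {
    stop("block_size must be at least 2^levels = ", 2L^levels)
  }
  if (brady_threshold_s <= 0 || tachy_threshold_s <= 0) {
    stop("alarm thresholds must be positive")
  }
  structure(list(block_size = block_size,
                 wavelet_config = wavelet_config(wavelet, levels, boundary),
                 peak_fraction = peak_fraction,
                 brady_threshold_s = brady_threshold_s,
                 tachy_threshold_s = tachy_threshold_s,
                 relative_band = relative_band,
                 brady_min_beats = as.integer(brady_min_beats),
                 warmup_s = warmup_s, refractory_s = refractory_s,
                 hrv_window_s = hrv_window_s, compress = compress,
                 bits = as.integer(bits), invert = invert),
            class = "pipeline_config")
}

# largest level count usable for a block of length m, capped at `levels`
.usable_levels <- function(m, levels) {
  if (m < 2L) return(0L)
  min(levels, floor(log2(m)))
}

.process_one_block <- function(blk, fs, cfg, run) {
  bi <- run$block_index
  k <- .usable_levels(length(blk), cfg$wavelet_config$levels)
  if (k < cfg$wavelet_config$levels) {
    run$log <- c(run$log, sprintf(
      "block %d: length %d short for %d levels, using %d",
      bi, length(blk), cfg$wavelet_config$levels, k))
  }
  pre <- blk
  if (k >= 1L) {
    wc <- wavelet_config(cfg$wavelet_config$wavelet, k,
                         cfg$wavelet_config$boundary)
    pre <- remove_baseline(blk, fs, config = wc)$corrected
    pre <- denoise(pre, wc)
  }
  det <- detect_r_peaks(pre, fs, peak_fraction = cfg$peak_fraction,
                        refractory_s = cfg$refractory_s,
                        state = run$det_state)
  run$det_state <- det$state
  if (nrow(det$peaks)) {
    run$peaks <- rbind(run$peaks, det$peaks)
    # feed new RR intervals to the incremental rhythm classifier
    tms <- c(run$last_peak_time, det$peaks$time_s)
    tms <- tms[!is.na(tms)]
    if (length(tms) >= 2) {
      rr <- diff(tms)
      ends <- tms[-1]
      for (q in seq_along(rr)) {
        run$rhythm_state <- .feed_rhythm(run$rhythm_state, rr[q], ends[q], bi,
                                         cfg$brady_threshold_s,
                                         cfg$tachy_threshold_s,
                                         cfg$brady_min_beats)
      }
    }
    run$last_peak_time <- det$peaks$time_s[nrow(det$peaks)]
  }
  if (cfg$compress && k >= 1L) {
    wc <- wavelet_config(cfg$wavelet_config$wavelet, k,
                         cfg$wavelet_config$boundary)
    run$compressed[[length(run$compressed) + 1L]] <-
      compress_block(blk, wc, bits = cfg$bits,
                     input_bit_depth = run$adc_resolution)
  }
  run$n_samples <- run$n_samples + length(blk)
  run$block_index <- bi + 1L
  run
}

#' Process an ECG record or block stream through the full chain
#'
#' Accepts a whole [ecg_signal()], a plain numeric vector, or a list of
#' numeric chunks (arbitrary sizes, e.g. as delivered by an acquisition
#' device). Input is re-buffered into `block_size`-sample blocks; each
#' block is baseline-corrected, denoised and scanned for R peaks, RR
#' intervals are classified for bradycardia/tachycardia, and the raw
#' block is optionally compressed. A final short block is processed
#' with as many wavelet levels as its length permits (logged in the
#' run report).
#'
#' @param source [ecg_signal()], numeric vector, or list of numeric
#'   chunks.
#' @param fs Sampling rate, required unless `source` is an
#'   `ecg_signal`.
#' @param config A [pipeline_config()].
#' @param adc_resolution Source ADC bits for compression accounting
#'   when `source` is not an `ecg_signal`.
#' @return List with `peaks` (data.frame), `rr` (`rr_series`), `alarms`
#'   (data.frame: `kind`, `onset_time_s`, `rr_values_s`,
#'   `block_index`), `irregular` (logical per interval), `hrv`
#'   (data.frame per `hrv_window_s` window), `compressed` (list of
#'   `compressed_block`), and `report` (record name, samples, blocks,
#'   alarm counts, mean heart rate, overall CR, log).
#' @export
#' @examples
#' g <- generate_ecg(synth_spec(duration_s = 20, seed = 3))
#' res <- process_stream(g$signal, config = pipeline_config())
#' res$report$n_blocks
process_stream <- function(source, fs = NULL, config = pipeline_config(),
                           adc_resolution = 16L) {
  record_name <- "stream"
  if (inherits(source, "ecg_signal")) {
    fs <- source$fs
    adc_resolution <- source$adc_resolution
    record_name <- source$record_name
    chunks <- list(source$samples)
  } else if (is.numeric(source)) {
    chunks <- list(as.numeric(source))
  } else if (is.list(source)) {
    chunks <- lapply(source, as.numeric)
  } else {
    stop("source must be an ecg_signal, numeric vector or list of chunks")
  }
  if (is.null(fs) || fs <= 0) stop("fs must be a positive sampling rate")

  run <- list(block_index = 0L, n_samples = 0L,
              det_state = rpeak_state(warmup_s = config$warmup_s,
                                      invert = config$invert),
              rhythm_state = rhythm_state(),
              peaks = data.frame(index = integer(0), time_s = numeric(0),
                                 amplitude = numeric(0)),
              last_peak_time = NA_real_, compressed = list(),
              adc_resolution = adc_resolution, log = character(0))

  buf <- numeric(0)
  for (ch in chunks) {
    buf <- c(buf, ch)
    while (length(buf) >= config$block_size) {
      run <- .process_one_block(buf[seq_len(config$block_size)], fs, config, run)
      buf <- buf[-seq_len(config$block_size)]
    }
  }
  if (length(buf)) run <- .process_one_block(buf, fs, config, run)
  run$rhythm_state <- .finalize_rhythm(run$rhythm_state, config$brady_min_beats)

  rr <- rr_intervals(run$peaks)
  alarms <- .events_df(run$rhythm_state$events)
  irregular <- ifelse(is.na(rr$rel_rr), NA, abs(rr$rel_rr) > config$relative_band)

  hrv <- data.frame(window_start_s = numeric(0), rmssd_ms = numeric(0),
                    sdnn_ms = numeric(0), n_intervals = integer(0))
  if (nrow(rr) >= 2) {
    win <- floor(rr$end_time_s / config$hrv_window_s)
    for (w in sort(unique(win))) {
      sel <- rr$rr_s[win == w]
      if (length(sel) >= 2) {
        hrv <- rbind(hrv, data.frame(
          window_start_s = w * config$hrv_window_s,
          rmssd_ms = sqrt(mean(diff(sel)^2)) * 1000,
          sdnn_ms = stats::sd(sel) * 1000,
          n_intervals = length(sel)))
      }
    }
  }

  total_in <- sum(vapply(run$compressed, `[[`, numeric(1), "input_bits"))
  total_out <- sum(vapply(run$compressed, `[[`, numeric(1), "output_bits"))
  total_pay <- sum(vapply(run$compressed, `[[`, numeric(1), "payload_bits"))
  report <- list(
    record_name = record_name, fs = fs,
    n_samples = run$n_samples, n_blocks = run$block_index,
    n_peaks = nrow(run$peaks),
    n_bradycardia = sum(alarms$kind == "bradycardia"),
    n_tachycardia = sum(alarms$kind == "tachycardia"),
    mean_hr_bpm = if (nrow(rr)) 60 / mean(rr$rr_s) else NA_real_,
    hrv = hrv_metrics(rr, sdann_window_s = config$hrv_window_s),
    cr = if (length(run$compressed)) total_in / total_out else NA_real_,
    cr_payload = if (length(run$compressed)) total_in / total_pay else NA_real_,
    log = run$log
  )
  list(peaks = run$peaks, rr = rr, alarms = alarms, irregular = irregular,
       hrv = hrv, compressed = run$compressed, report = report)
}
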