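# Personalized R-peak detection, RR-interval analysis, bradycardia and
# tachycardia alarms, HRV metrics.
#
# The detector is amplitude based and personalized: after a 2 s warm-up
# (long enough to contain at least one heartbeat at neonatal rates) the
# largest value seen so far becomes the reference peak, and candidate
# local maxima below 70% of the reference are rejected. The reference
# is a per-block running maximum carried across blocks with a mild
# exponential decay, so it follows the infant's amplitude drift in both
# directions instead of ratcheting upward forever.

#' Fresh R-peak detector state
#'
#' Holds everything the detector must carry across 1000-sample blocks:
#' the global sample offset, the adaptive reference amplitude, the time
#' of the last accepted peak (for the refractory rule) and the trailing
#' raw samples needed to judge local maxima at block boundaries.
#'
#' @param warmup_s Warm-up during which no peaks are reported and the
#'   reference is being established (default 2 s).
#' @param ref_decay Multiplicative decay of the carried reference per
#'   block (default 0.99).
#' @param invert Set `TRUE` for inverted leads (negative R waves); the
#'   signal is negated before detection.
#' @return Object of class `rpeak_state`.
#' @export
rpeak_state <- function(warmup_s = 2, ref_decay = 0.99, invert = FALSE) {
  structure(list(offset = 0L, reference = -Inf, last_peak_time = -Inf,
                 tail_samples = numeric(0), warmup_s = warmup_s,
                 ref_decay = ref_decay, invert = invert),
            class = "rpeak_state")
}

#' Detect R peaks with a personalized amplitude reference
#'
#' Finds local maxima (strictly greater than both neighbours; plateau
#' ties resolve to the leftmost sample) whose amplitude is at least
#' `peak_fraction` of the adaptive reference peak, separated by at
#' least the refractory period. Peaks inside the initial warm-up window
#' are never reported. Call repeatedly with the returned `state` to
#' process a record block by block; peaks at block boundaries are
#' handled through the carried tail samples.
#'
#' @param x Numeric samples of one block (preprocessed ECG), or an
#'   [ecg_signal()].
#' @param fs Sampling rate in Hz (taken from the signal object if one
#'   is given).
#' @param peak_fraction Fraction of the reference peak below which
#'   candidates are rejected (default 0.7).
#' @param refractory_s Minimum spacing between accepted peaks (default
#'   0.2 s, below the shortest plausible neonatal RR of ~0.3 s).
#' @param state A `rpeak_state` carried from the previous block, or
#'   `NULL` to start a fresh record.
#' @return List with `peaks` (data.frame: `index` 0-based global sample
#'   position, `time_s`, `amplitude`), `reference` (the reference peak
#'   after this block) and `state` to pass to the next call.
#' @export
#' @examples
#' g <- generate_ecg(synth_spec(duration_s = 10, seed = 2))
#' det <- detect_r_peaks(g$signal)
#' nrow(det$peaks)
detect_r_peaks <- function(x, fs = NULL, peak_fraction = 0.7,
                           refractory_s = 0.2, state = NULL) {
  if (inherits(x, "ecg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  x <- as.numeric(x)
  if (is.null(state)) state <- rpeak_state()
  if (state$invert) x <- -x
  empty <- data.frame(index = integer(0), time_s = numeric(0),
                      amplitude = numeric(0))
  if (length(x) == 0) {
    return(list(peaks = empty, reference = state$reference, state = state))
  }

  ntail <- length(state$tail_samples)
  ext <- c(state$tail_samples, x)          # tail carries boundary maxima
  base <- state$offset - ntail             # global 0-based index of ext[1]

  # reference peak: this block's maximum, or the decayed carry if larger
  ref <- max(state$reference * state$ref_decay, max(x))

  m <- length(ext)
  cand <- integer(0)
  if (m >= 3) {
    i <- 2:(m - 1)
    is_max <- ext[i] > ext[i - 1] & ext[i] >= ext[i + 1]
    # leftmost-of-plateau: strict rise on the left, fall (possibly after
    # a flat run) on the right
    plateau_ok <- logical(length(i))
    runs <- which(is_max)
    for (r in runs) {
      j <- i[r]
      k <- j
      while (k < m && ext[k + 1] == ext[j]) k <- k + 1
      plateau_ok[r] <- k == m || ext[k + 1] < ext[j]
    }
    cand <- i[is_max & plateau_ok]
  }

  peaks <- empty
  last_t <- state$last_peak_time
  if (length(cand)) {
    gidx <- base + cand - 1               # global 0-based sample index
    tms <- gidx / fs
    amp <- ext[cand]
    keep <- tms >= state$warmup_s & gidx >= state$offset - 1 &
      amp >= peak_fraction * ref & ref > 0
    acc <- logical(length(cand))
    for (q in which(keep)) {
      if (tms[q] - last_t >= refractory_s) {
        acc[q] <- TRUE
        last_t <- tms[q]
      }
    }
    if (any(acc)) {
      peaks <- data.frame(index = as.integer(gidx[acc]), time_s = tms[acc],
                          amplitude = amp[acc])
    }
  }
  if (state$invert) peaks$amplitude <- -peaks$amplitude

  state$offset <- state$offset + length(x)
  state$reference <- ref
  state$last_peak_time <- last_t
  state$tail_samples <- if (state$invert) {
    -utils::tail(ext, 2L)
  } else {
    utils::tail(ext, 2L)
  }
  list(peaks = peaks, reference = ref, state = state)
}

#' RR intervals and relative RR from detected peaks
#'
#' `rr[j]` is the spacing between consecutive peak times. The relative
#' RR normalizes each successive change,
#' `rel_rr[j] = 2 (rr[j] - rr[j-1]) / (rr[j] + rr[j-1])`, a
#' dimensionless quantity algebraically confined to (-2, 2); values
#' beyond about +-0.2 mark rhythm irregularity. It is defined from the
#' second interval on (`NA` for the first).
#'
#' @param peaks data.frame with a `time_s` column (as returned by
#'   [detect_r_peaks()]), or a numeric vector of peak times in seconds.
#' @return Object of class `rr_series`: data.frame with columns `rr_s`,
#'   `rel_rr` and `end_time_s` (time of the beat closing the interval);
#'   zero rows when fewer than two peaks are available.
#' @export
rr_intervals <- function(peaks) {
  tms <- if (is.data.frame(peaks)) peaks$time_s else as.numeric(peaks)
  if (length(tms) < 2) {
    out <- data.frame(rr_s = numeric(0), rel_rr = numeric(0),
                      end_time_s = numeric(0))
    class(out) <- c("rr_series", "data.frame")
    return(out)
  }
  rr <- diff(tms)
  rel <- c(NA_real_, 2 * diff(rr) / (rr[-length(rr)] + rr[-1]))
  out <- data.frame(rr_s = rr, rel_rr = rel, end_time_s = tms[-1])
  class(out) <- c("rr_series", "data.frame")
  out
}

# incremental rhythm classifier ------------------------------------------

#' Fresh rhythm classifier state
#'
#' Carries open bradycardia/tachycardia runs across block boundaries so
#' that an episode spanning two blocks raises exactly one alarm.
#'
#' @keywords internal
#' @export
rhythm_state <- function() {
  structure(list(brady_run = list(), tachy_run = list(),
                 events = list()), class = "rhythm_state")
}

.close_run <- function(state, kind, min_len = 1L, block_index = NA_integer_) {
  fld <- paste0(kind, "_run")
  run <- state[[fld]]
  if (length(run) >= min_len) {
    state$events[[length(state$events) + 1L]] <- list(
      kind = if (kind == "brady") "bradycardia" else "tachycardia",
      onset_time_s = run[[1]]$end_time_s,
      rr_values_s = vapply(run, `[[`, numeric(1), "rr_s"),
      block_index = run[[1]]$block_index
    )
  }
  state[[fld]] <- list()
  state
}

.feed_rhythm <- function(state, rr_s, end_time_s, block_index,
                         brady_threshold, tachy_threshold, brady_min_beats) {
  itm <- list(rr_s = rr_s, end_time_s = end_time_s, block_index = block_index)
  if (rr_s > brady_threshold) {
    state$brady_run[[length(state$brady_run) + 1L]] <- itm
  } else {
    state <- .close_run(state, "brady", brady_min_beats)
  }
  if (rr_s < tachy_threshold) {
    state$tachy_run[[length(state$tachy_run) + 1L]] <- itm
  } else {
    state <- .close_run(state, "tachy", 2L)
  }
  state
}

.finalize_rhythm <- function(state, brady_min_beats) {
  state <- .close_run(state, "brady", brady_min_beats)
  state <- .close_run(state, "tachy", 2L)
  state
}

.events_df <- function(events) {
  if (!length(events)) {
    return(data.frame(kind = character(0), onset_time_s = numeric(0),
                      rr_values_s = I(list()), block_index = integer(0)))
  }
  data.frame(
    kind = vapply(events, `[[`, character(1), "kind"),
    onset_time_s = vapply(events, `[[`, numeric(1), "onset_time_s"),
    rr_values_s = I(lapply(events, `[[`, "rr_values_s")),
    block_index = vapply(events, function(e) {
      as.integer(e$block_index %||% NA_integer_)
    }, integer(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bradycardia / tachycardia alarms and irregularity flags
#'
#' Applies the RR-interval decision rules: an RR interval strictly
#' greater than `brady_threshold` (default 0.6 s, i.e. instantaneous
#' rate below 100 bpm) signals bradycardia -- one alarm per maximal run
#' of such intervals, carrying every triggering RR value. Tachycardia
#' (rate above 140 bpm) requires at least two consecutive intervals
#' strictly below `tachy_threshold` (default 0.43 s). Intervals whose
#' relative RR magnitude exceeds `relative_band` are flagged irregular.
#'
#' @param rr An `rr_series` from [rr_intervals()].
#' @param brady_threshold Bradycardia RR bound in seconds (default
#'   `60/100 = 0.6`).
#' @param tachy_threshold Tachycardia RR bound in seconds (default
#'   `60/140` rounded to 0.43).
#' @param relative_band Irregularity band on `|rel_rr|` (default 0.20).
#' @param brady_min_beats Minimum run length for a bradycardia alarm.
#'   Default 1 (alert on any single long interval); set 2 for the
#'   stricter clinical definition of rate < 100 bpm for at least two
#'   beats.
#' @return List with `events` (data.frame: `kind`, `onset_time_s`,
#'   `rr_values_s` list column, `block_index`) and `irregular` (logical
#'   per interval, `NA` where `rel_rr` is undefined).
#' @export
#' @examples
#' rr <- rr_intervals(c(0, 0.45, 1.12, 1.62))
#' classify_rhythm(rr)$events
classify_rhythm <- function(rr, brady_threshold = 0.6, tachy_threshold = 0.43,
                            relative_band = 0.20, brady_min_beats = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  st <- rhythm_state()
  for (j in seq_len(nrow(rr))) {
    st <- .feed_rhythm(st, rr$rr_s[j], rr$end_time_s[j], NA_integer_,
                       brady_threshold, tachy_threshold, brady_min_beats)
  }
  st <- .finalize_rhythm(st, brady_min_beats)
  list(events = .events_df(st$events),
       irregular = ifelse(is.na(rr$rel_rr), NA, abs(rr$rel_rr) > relative_band))
}

#' Heart rate variability metrics
#'
#' Standard short-term HRV metrics in milliseconds: RMSSD (root mean
#' square of successive RR differences), SDNN (sample standard
#' deviation of the RR intervals) and SDANN (sample standard deviation
#' of mean RR per time window). Short windows (2 s or 5 s) suit
#' block-wise neonatal monitoring where rhythm changes must surface
#' quickly; classical SDANN uses 5 min windows on long recordings.
#'
#' @param rr An `rr_series` or numeric vector of RR intervals in
#'   seconds (for a bare vector, interval end times are taken as the
#'   cumulative sum).
#' @param sdann_window_s Window length for SDANN in seconds (default 5).
#' @return Named list `rmssd_ms`, `sdnn_ms`, `sdann_ms`; a metric whose
#'   preconditions fail (fewer than 2 intervals, fewer than 2 occupied
#'   windows) is `NA`, never silently 0.
#' @export
#' @examples
#' hrv_metrics(c(0.67, 0.68, 0.67))$rmssd_ms  # 10
hrv_metrics <- function(rr, sdann_window_s = 5) {
  if (inherits(rr, "rr_series") || is.data.frame(rr)) {
    rr_s <- rr$rr_s
    end_t <- rr$end_time_s
  } else {
    rr_s <- as.numeric(rr)
    end_t <- cumsum(rr_s)
  }
  n <- length(rr_s)
  rmssd <- if (n >= 2) sqrt(mean(diff(rr_s)^2)) * 1000 else NA_real_
  sdnn <- if (n >= 2) stats::sd(rr_s) * 1000 else NA_real_
  sdann <- NA_real_
  if (n >= 2) {
    win <- floor(end_t / sdann_window_s)
    means <- tapply(rr_s, win, mean)
    if (length(means) >= 2) sdann <- stats::sd(means) * 1000
  }
  list(rmssd_ms = rmssd, sdnn_ms = sdnn, sdann_ms = sdann)
}

#' Match alarm times against annotated event times
#'
#' Greedy one-to-one matching within a time tolerance, for evaluating
#' detector output against reference annotations.
#'
#' @param alarm_times,annotation_times Numeric vectors of event times
#'   in seconds.
#' @param tolerance_s Maximum |alarm - annotation| for a match
#'   (default 5 s).
#' @return List with `n_matched`, `sensitivity`, `ppv` and the matched
#'   index pairs.
#' @export
match_events <- function(alarm_times, annotation_times, tolerance_s = 5) {
  alarm_times <- sort(alarm_times)
  annotation_times <- sort(annotation_times)
  used <- logical(length(alarm_times))
  pairs <- NULL
  for (i in seq_along(annotation_times)) {
    d <- abs(alarm_times - annotation_times[i])
    d[used] <- Inf
    if (length(d) && min(d) <= tolerance_s) {
      j <- which.min(d)
      used[j] <- TRUE
      pairs <- rbind(pairs, c(annotation = i, alarm = j))
    }
  }
  nm <- sum(used)
  list(
    n_matched = nm,
    sensitivity = if (length(annotation_times)) nm / length(annotation_times) else NA_real_,
    ppv = if (length(alarm_times)) nm / length(alarm_times) else NA_real_,
    pairs = pairs
  )
}
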