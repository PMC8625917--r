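# Synthetic neonatal ECG with ground-truth beat positions. Emulates the
# gross characteristics of preterm-infant chest-lead recordings: QRS
# complexes at 100-180 bpm, injectable bradycardia pauses (RR > 0.6 s),
# sub-1 Hz baseline wander, additive white noise and 50/60 Hz mains
# pickup. Not a physiological model -- the QRS is a fixed Gaussian
# second-derivative pulse -- but sufficient for end-to-end testing of
# detection, denoising and compression with exact ground truth.

#' Specification of a synthetic neonatal ECG recording
#'
#' @param fs Sampling rate in Hz (250 or 500, the rates of bedside
#'   neonatal monitors; others are allowed but warned about).
#' @param duration_s Record length in seconds.
#' @param base_hr_bpm Baseline heart rate in beats per minute (neonatal
#'   default 150).
#' @param hr_profile Optional data.frame with columns `start_s` and
#'   `bpm`: piecewise-constant heart-rate segments overriding
#'   `base_hr_bpm` from each `start_s` onward.
#' @param brady_episodes Optional data.frame with columns `start_s`,
#'   `n_beats`, `rr_s` (`rr_s > 0.6`): from the first beat at or after
#'   `start_s`, the next `n_beats` RR intervals are set to `rr_s`.
#'   Episodes must not overlap and must end inside the record.
#' @param qrs_width_ms Width parameter of the Gaussian-derivative QRS
#'   pulse (default 40 ms).
#' @param qrs_amplitude_mv R-peak amplitude in mV (default 1.0).
#' @param baseline_mv,baseline_hz Amplitude (mV) and frequency (< 1 Hz)
#'   of sinusoidal baseline wander; 0 disables.
#' @param noise_sd_mv Standard deviation of additive white Gaussian
#'   noise in mV; 0 disables.
#' @param powerline_mv,powerline_hz Amplitude (mV) and frequency (50 or
#'   60 Hz) of mains interference; 0 disables.
#' @param rr_jitter_sd_s Standard deviation of zero-mean Gaussian jitter
#'   added to non-episode RR intervals (default 0: deterministic beat
#'   grid).
#' @param seed Integer seed; the generator draws all randomness from
#'   one stream so equal specs give bit-identical records.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 250, duration_s = 60, base_hr_bpm = 150,
                       hr_profile = NULL, brady_episodes = NULL,
                       qrs_width_ms = 40, qrs_amplitude_mv = 1.0,
                       baseline_mv = 0, baseline_hz = 0.3,
                       noise_sd_mv = 0, powerline_mv = 0, powerline_hz = 50,
                       rr_jitter_sd_s = 0, seed = 1L) {
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  if (!fs %in% c(250, 500)) {
    warning("fs = ", fs, " Hz is outside the usual neonatal monitor rates")
  }
  if (baseline_mv > 0 && baseline_hz >= 1) {
    stop("baseline wander frequency must be below 1 Hz")
  }
  if (any(c(qrs_amplitude_mv, baseline_mv, noise_sd_mv, powerline_mv) < 0)) {
    stop("amplitudes must be nonnegative")
  }
  if (!is.null(brady_episodes)) {
    be <- as.data.frame(brady_episodes)
    stopifnot(all(c("start_s", "n_beats", "rr_s") %in% names(be)))
    if (any(be$rr_s <= 0.6)) {
      stop("bradycardia episode rr_s must exceed 0.6 s")
    }
    be <- be[order(be$start_s), , drop = FALSE]
    ends <- be$start_s + be$n_beats * be$rr_s
    if (any(ends > duration_s)) stop("bradycardia episode extends past record end")
    if (nrow(be) > 1 && any(be$start_s[-1] < ends[-nrow(be)])) {
      stop("bradycardia episodes overlap")
    }
    brady_episodes <- be
  }
  if (!is.null(hr_profile)) {
    hr_profile <- as.data.frame(hr_profile)
    stopifnot(all(c("start_s", "bpm") %in% names(hr_profile)))
    hr_profile <- hr_profile[order(hr_profile$start_s), , drop = FALSE]
  }
  structure(list(fs = fs, duration_s = duration_s, base_hr_bpm = base_hr_bpm,
                 hr_profile = hr_profile, brady_episodes = brady_episodes,
                 qrs_width_ms = qrs_width_ms,
                 qrs_amplitude_mv = qrs_amplitude_mv,
                 baseline_mv = baseline_mv, baseline_hz = baseline_hz,
                 noise_sd_mv = noise_sd_mv, powerline_mv = powerline_mv,
                 powerline_hz = powerline_hz,
                 rr_jitter_sd_s = rr_jitter_sd_s, seed = as.integer(seed)),
            class = "synth_spec")
}

.hr_at <- function(spec, t) {
  bpm <- spec$base_hr_bpm
  if (!is.null(spec$hr_profile)) {
    seg <- spec$hr_profile[spec$hr_profile$start_s <= t, , drop = FALSE]
    if (nrow(seg) > 0) bpm <- seg$bpm[nrow(seg)]
  }
  bpm
}

#' Generate a synthetic neonatal ECG with ground truth
#'
#' Beat times are laid down sequentially from the heart-rate profile;
#' inside a bradycardia episode the requested RR value is used verbatim,
#' so every injected episode appears exactly in the ground-truth RR
#' sequence. Each beat contributes a Gaussian second-derivative
#' ("Ricker") pulse whose maximum sits at the beat time; wander, noise
#' and mains terms are added afterwards and do not move the true peaks.
#'
#' @param spec A [synth_spec()].
#' @return List with `signal` (an [ecg_signal()]) and `truth`, a list
#'   holding `peak_times` (s), `rr` (s) and `brady_intervals`
#'   (data.frame `start_s`, `end_s`, one row per injected episode).
#' @export
#' @examples
#' g <- generate_ecg(synth_spec(duration_s = 10, seed = 7))
#' length(g$truth$peak_times)
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)

  # beat grid
  beats <- numeric(0)
  t <- 0.5 / (spec$base_hr_bpm / 60)  # first beat half an interval in
  ep <- spec$brady_episodes
  ep_row <- if (is.null(ep)) 0L else 1L
  ep_left <- 0L
  ep_rr <- NA_real_
  brady_iv <- list()
  iv_start <- NA_real_
  while (t < spec$duration_s) {
    beats <- c(beats, t)
    if (ep_left == 0L && ep_row > 0L && ep_row <= NROW(ep) &&
        t >= ep$start_s[ep_row]) {
      ep_left <- ep$n_beats[ep_row]
      ep_rr <- ep$rr_s[ep_row]
      iv_start <- t
      ep_row <- ep_row + 1L
    }
    if (ep_left > 0L) {
      rr <- ep_rr
      ep_left <- ep_left - 1L
      if (ep_left == 0L) {
        brady_iv[[length(brady_iv) + 1L]] <- c(iv_start, t + rr)
      }
    } else {
      rr <- 60 / .hr_at(spec, t)
      if (spec$rr_jitter_sd_s > 0) {
        rr <- max(0.25, rr + stats::rnorm(1, 0, spec$rr_jitter_sd_s))
      }
    }
    t <- t + rr
  }
  # drop a trailing beat whose QRS would be clipped by the record end
  w_s <- spec$qrs_width_ms / 1000
  beats <- beats[beats < spec$duration_s - 2 * w_s]

  n <- round(spec$duration_s * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  x <- numeric(n)
  sigma <- w_s / 4  # +-2 sigma spans the nominal QRS width
  for (b in beats) {
    lo <- max(1L, floor((b - 5 * sigma) * spec$fs) + 1L)
    hi <- min(n, ceiling((b + 5 * sigma) * spec$fs) + 1L)
    u <- (tt[lo:hi] - b) / sigma
    x[lo:hi] <- x[lo:hi] + spec$qrs_amplitude_mv * (1 - u^2) * exp(-u^2 / 2)
  }
  if (spec$baseline_mv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + spec$baseline_mv * sin(2 * pi * spec$baseline_hz * tt + phase)
  }
  if (spec$powerline_mv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + spec$powerline_mv * sin(2 * pi * spec$powerline_hz * tt + phase)
  }
  if (spec$noise_sd_mv > 0) {
    x <- x + stats::rnorm(n, 0, spec$noise_sd_mv)
  }

  truth <- list(
    peak_times = beats,
    rr = if (length(beats) >= 2) diff(beats) else numeric(0),
    brady_intervals = if (length(brady_iv)) {
      data.frame(start_s = vapply(brady_iv, `[`, numeric(1), 1L),
                 end_s = vapply(brady_iv, `[`, numeric(1), 2L))
    } else {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    }
  )
  list(signal = ecg_signal(x, fs = spec$fs, record_name = "synthetic"),
       truth = truth)
}
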