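# Record I/O: WFDB signal records (.hea header + format-16 .dat),
# two-column CSV, WFDB MIT-format annotation files and plain-text
# annotation lists.

#' Single-lead ECG container
#'
#' @param samples Numeric amplitude samples in physical units (mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param adc_resolution ADC word length in bits, 8--32 (default 16).
#' @param record_name Record identifier.
#' @param start_offset_s Time of the first sample relative to the start
#'   of the source recording, in seconds.
#' @return Object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs, adc_resolution = 16L,
                       record_name = "record", start_offset_s = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite")
  }
  adc_resolution <- as.integer(adc_resolution)
  if (adc_resolution < 8L || adc_resolution > 32L) {
    stop("adc_resolution must be in [8, 32] bits")
  }
  structure(list(samples = samples, fs = fs,
                 adc_resolution = adc_resolution,
                 record_name = record_name,
                 start_offset_s = start_offset_s),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ecg_signal '%s': %d samples @ %g Hz (%.1f s), %d-bit ADC\n",
              x$record_name, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$adc_resolution))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

# parse a WFDB .hea file; single-segment records, enough fields for
# PhysioNet ECG records (format, gain(baseline)/units, ADC resolution)
.read_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("missing WFDB header: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed WFDB header (empty): ", hea_path)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) stop("malformed WFDB record line in ", hea_path)
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*", "", rec[3]))  # strip counter frequency
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  if (is.na(nsig) || is.na(fs) || fs <= 0) {
    stop("malformed WFDB record line in ", hea_path)
  }
  if (length(lines) < 1 + nsig) stop("WFDB header lists ", nsig,
                                     " signals but has too few lines")
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*", "", gain_spec))
    gain <- as.numeric(gain_num)
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default adu/mV
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_spec))
    } else {
      NA_real_
    }
    adc_res <- if (length(f) >= 4) as.integer(f[4]) else 12L
    adc_zero <- if (length(f) >= 5) as.integer(f[5]) else 0L
    if (is.na(baseline)) baseline <- adc_zero
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         adc_res = adc_res, adc_zero = adc_zero,
         desc = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else "")
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a single-lead ECG record
#'
#' Reads one channel of a WFDB record (header `.hea` plus interleaved
#' little-endian format-16 `.dat`, the layout of the PhysioNet neonatal
#' records) or a two-column CSV (`time_s`, `amplitude_mv`, header row).
#' WFDB digital values convert to physical mV through the header's
#' affine gain/baseline; CSV amplitudes are taken as already physical.
#'
#' @param path Record path. For WFDB, with or without the `.hea`
#'   extension; for CSV, the `.csv` file.
#' @param format `"wfdb"` or `"csv"` (guessed from the extension when
#'   missing).
#' @param channel 0-based signal index within a multi-channel WFDB
#'   record (default 0).
#' @param window Optional `c(start_s, duration_s)` half-open window
#'   `[start, start + duration)` to extract.
#' @param fs Sampling rate, required for CSV input lacking a usable
#'   time column; for CSV with a time column it is inferred.
#' @param adc_resolution ADC resolution assumed for CSV input (default
#'   16 bits).
#' @return An [ecg_signal()] in mV.
#' @export
read_ecg <- function(path, format = c("auto", "wfdb", "csv"), channel = 0L,
                     window = NULL, fs = NULL, adc_resolution = 16L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    return(.read_ecg_csv(path, window = window, fs = fs,
                         adc_resolution = adc_resolution))
  }
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  hdr <- .read_wfdb_header(hea_path)
  channel <- as.integer(channel)
  if (channel < 0L || channel >= hdr$nsig) {
    stop("channel ", channel, " out of range: record has ", hdr$nsig,
         " signal(s)")
  }
  sig <- hdr$signals[[channel + 1L]]
  if (sig$format != "16") {
    stop("unsupported WFDB signal format '", sig$format,
         "' (only format 16 is implemented)")
  }
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) stop("missing WFDB signal file: ", dat_path)
  n_tot <- file.info(dat_path)$size / 2 / hdr$nsig
  raw <- readBin(dat_path, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = hdr$nsig * floor(n_tot))
  adu <- raw[seq(channel + 1L, length(raw), by = hdr$nsig)]
  mv <- (adu - sig$baseline) / sig$gain
  start_s <- 0
  if (!is.null(window)) {
    w <- .window_index(window, hdr$fs, length(mv))
    mv <- mv[w]
    start_s <- window[1]
  }
  ecg_signal(mv, fs = hdr$fs, adc_resolution = sig$adc_res,
             record_name = hdr$record, start_offset_s = start_s)
}

.window_index <- function(window, fs, n) {
  if (length(window) != 2 || any(window < 0)) {
    stop("window must be c(start_s, duration_s), both nonnegative")
  }
  i0 <- floor(window[1] * fs) + 1L
  i1 <- min(n, floor((window[1] + window[2]) * fs))
  if (i0 > n) stop("window starts beyond the end of the record")
  seq.int(i0, i1)
}

.read_ecg_csv <- function(path, window = NULL, fs = NULL,
                          adc_resolution = 16L) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("malformed ECG CSV (need time_s, amplitude_mv): ", path)
  tms <- d[[1]]
  mv <- d[[2]]
  if (is.null(fs)) {
    dt <- diff(tms)
    if (length(dt) < 1 || any(dt <= 0)) stop("cannot infer fs from time column")
    fs <- 1 / stats::median(dt)
    fs <- round(fs, 6)
  }
  start_s <- 0
  if (!is.null(window)) {
    w <- .window_index(window, fs, length(mv))
    mv <- mv[w]
    start_s <- window[1]
  }
  ecg_signal(mv, fs = fs, adc_resolution = adc_resolution,
             record_name = sub("\\.csv$", "", basename(path), ignore.case = TRUE),
             start_offset_s = start_s)
}

#' Write an ECG signal as CSV
#'
#' Two columns, `time_s` and `amplitude_mv`, header row, UTF-8 -- the
#' dialect [read_ecg()] accepts.
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  d <- data.frame(time_s = signal$start_offset_s + (seq_len(n) - 1) / signal$fs,
                  amplitude_mv = signal$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read event annotations
#'
#' Reads reference event times for evaluation against alarm output.
#' Two formats: WFDB MIT-format binary annotation files (e.g. the
#' PhysioNet bradycardia annotations) and plain text with one event
#' time in seconds per line (`#` comments allowed).
#'
#' @param path Annotation file.
#' @param fs Sampling rate of the annotated record, required for the
#'   MIT format (annotation times are stored in samples).
#' @param format `"auto"` (MIT when the file is binary), `"mit"` or
#'   `"text"`.
#' @return Sorted numeric vector of event times in seconds.
#' @export
read_annotations <- function(path, fs = NULL,
                             format = c("auto", "mit", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing annotation file: ", path)
  if (format == "auto") {
    probe <- readBin(path, "raw", n = 512)
    format <- if (length(probe) &&
                  any(probe > as.raw(127) | probe == as.raw(0)))
      "mit" else "text"
  }
  if (format == "text") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(numeric(0))
    tms <- suppressWarnings(as.numeric(lines))
    if (anyNA(tms)) stop("malformed text annotation file: ", path)
    return(sort(tms))
  }
  if (is.null(fs)) stop("fs is required to convert MIT annotation samples to seconds")
  .read_mit_annotations(path, fs)
}

# MIT annotation stream: 2-byte little-endian words; code = word >> 10,
# interval = word & 0x3FF samples since the previous annotation.
# Pseudo-codes: 59 SKIP (4-byte long interval follows), 60 NUM, 61 SUB,
# 62 CHN, 63 AUX (byte count follows, padded to even); word 0 ends.
.read_mit_annotations <- function(path, fs) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  i <- 1L
  t_samp <- 0
  times <- numeric(0)
  nb <- length(b)
  while (i + 1L <= nb) {
    lo <- as.integer(b[i]); hi <- as.integer(b[i + 1L])
    word <- lo + 256L * hi
    i <- i + 2L
    code <- word %/% 1024L
    interval <- word %% 1024L
    if (word == 0L) break
    if (code == 59L) {                 # SKIP: next 4 bytes = long interval
      if (i + 3L > nb) stop("truncated SKIP in MIT annotation file")
      hi2 <- as.integer(b[i]) + 256L * as.integer(b[i + 1L])
      lo2 <- as.integer(b[i + 2L]) + 256L * as.integer(b[i + 3L])
      long_iv <- hi2 * 65536 + lo2
      if (long_iv >= 2^31) long_iv <- long_iv - 2^32
      t_samp <- t_samp + long_iv
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance
    } else if (code == 63L) {          # AUX string, padded to even length
      i <- i + interval + interval %% 2L
    } else if (code >= 1L && code <= 49L) {
      t_samp <- t_samp + interval
      times <- c(times, t_samp / fs)
    } else {
      stop("unrecognized MIT annotation code ", code)
    }
  }
  sort(times)
}

#' Write alarm events as JSON lines
#'
#' One JSON object per line: `kind`, `onset_time_s`, `rr_values_s`,
#' `block_index`.
#'
#' @param events Alarm data.frame as produced by [classify_rhythm()] or
#'   [process_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alarms_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(nrow(events))) {
    rec <- list(kind = events$kind[j],
                onset_time_s = events$onset_time_s[j],
                rr_values_s = as.numeric(events$rr_values_s[[j]]),
                block_index = events$block_index[j])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read alarm events from JSON lines
#'
#' @param path JSON-lines file written by [write_alarms_jsonl()].
#' @return data.frame with `kind`, `onset_time_s`, `rr_values_s` (list
#'   column), `block_index`.
#' @export
read_alarms_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(kind = character(0), onset_time_s = numeric(0),
                      rr_values_s = I(list()), block_index = integer(0)))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    kind = vapply(recs, `[[`, character(1), "kind"),
    onset_time_s = vapply(recs, `[[`, numeric(1), "onset_time_s"),
    rr_values_s = I(lapply(recs, function(r) as.numeric(r$rr_values_s))),
    block_index = vapply(recs, function(r) {
      as.integer(r$block_index %||% NA_integer_)
    }, integer(1))
  )
}
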