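# Undecimated (stationary) wavelet transform -- "algorithme a trous".
# All convolutions are circular; at level j the analysis filters are the
# base filters with 2^(j-1) - 1 zeros inserted between taps, so every
# coefficient array keeps the full signal length (no decimation).

# Orthonormal Daubechies scaling filters, ascending-index convention,
# sum(h) = sqrt(2). Only the families a neonatal ECG chain plausibly
# uses are shipped; db8 is the default analysis wavelet.
.scaling_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153,
          0.63088076792959036, -0.02798376941698385,
          -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728),
  db8 = c(0.05441584224310401, 0.31287159091429995,
          0.67563073629728980, 0.58535468365420670,
          -0.01582910525634931, -0.28401554296154690,
          0.00047248457391328, 0.12874742662047847,
          -0.01736930100180755, -0.04408825393079475,
          0.01398102791739828, 0.00874609404740578,
          -0.00487035299345157, -0.00039174037337695,
          0.00067544940645057, -0.00011747678412477)
)

#' Analysis filter pair for a named wavelet
#'
#' Returns the orthonormal low-pass (scaling) filter `h` and the
#' quadrature mirror high-pass filter `g`, with
#' `g[k] = (-1)^k h[L - 1 - k]` (0-based `k`). The pair is power
#' complementary, `|H(w)|^2 + |G(w)|^2 = 2`, which is what makes the
#' redundant transform below exactly invertible.
#'
#' @param wavelet Wavelet name, one of `"db2"`, `"db4"`, `"db8"`.
#' @return List with numeric vectors `h` (low-pass) and `g` (high-pass).
#' @export
#' @examples
#' f <- wavelet_filters("db8")
#' sum(f$h)  # sqrt(2)
wavelet_filters <- function(wavelet = "db8") {
  h <- .scaling_filters[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.scaling_filters), collapse = ", "))
  }
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

#' Wavelet decomposition configuration
#'
#' @param wavelet Mother wavelet name (default `"db8"`).
#' @param levels Number of decomposition levels `k >= 1` (default 5).
#' @param boundary Boundary handling: `"periodic"` (circular, the
#'   classical a trous setting, exactly shift invariant) or
#'   `"symmetric"` (signal reflected to twice its length before the
#'   periodic transform, reducing wrap-around artifacts on blocks whose
#'   ends do not match).
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet = "db8", levels = 5L,
                           boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop("levels must be a positive integer")
  wavelet_filters(wavelet)  # validates the name
  structure(list(wavelet = wavelet, levels = levels, boundary = boundary),
            class = "wavelet_config")
}

#' @export
print.wavelet_config <- function(x, ...) {
  cat(sprintf("wavelet_config: %s, %d level(s), %s boundary\n",
              x$wavelet, x$levels, x$boundary))
  invisible(x)
}

# Circular correlation with an upsampled filter: y[t] = sum_k f[k] x[t + s*k]
# (s = 2^(level-1)). Implemented as a sum of circularly shifted copies.
.acorr <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n) - 1L
  for (k in seq_along(f)) {
    sh <- ((idx + s * (k - 1L)) %% n) + 1L
    y <- y + f[k] * x[sh]
  }
  y
}

# Circular convolution with an upsampled filter: y[t] = sum_k f[k] x[t - s*k]
.aconv <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n) - 1L
  for (k in seq_along(f)) {
    sh <- ((idx - s * (k - 1L)) %% n) + 1L
    y <- y + f[k] * x[sh]
  }
  y
}

#' Stationary wavelet decomposition
#'
#' Decomposes a signal into full-length detail coefficient arrays
#' `cD_1 .. cD_k` and the final approximation `cA_k` using the
#' undecimated a trous scheme: the signal passes successively through
#' the low-pass branch, and at every level the filters are dilated by
#' inserting zeros between taps. In periodic mode the transform is
#' exactly shift invariant (circular shifts of the input circularly
#' shift every coefficient array).
#'
#' @param x Numeric signal, all values finite, `length(x) >= 2^levels`.
#' @param config A [wavelet_config()].
#' @return Object of class `swt_coeffs`: list with `details` (list of
#'   `k` numeric vectors), `approximation`, `config`, `n` (original
#'   signal length) and `n_ext` (coefficient array length; equals `n`
#'   in periodic mode and `2n` in symmetric mode, where the reflected
#'   extension is retained so that reconstruction stays exact).
#' @seealso [swt_reconstruct()], [energy_distribution()]
#' @export
#' @examples
#' x <- sin(2 * pi * 7 * seq(0, 2, by = 1 / 250))
#' co <- swt_decompose(x, wavelet_config(levels = 3))
#' max(abs(swt_reconstruct(co) - x))  # ~1e-16
swt_decompose <- function(x, config = wavelet_config()) {
  if (!inherits(config, "wavelet_config")) stop("config must be a wavelet_config")
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("signal contains non-finite samples")
  n <- length(x)
  k <- config$levels
  if (n < 2^k) {
    stop(sprintf("signal of length %d too short for %d levels (need >= %d)",
                 n, k, 2^k))
  }
  work <- if (config$boundary == "symmetric") c(x, rev(x)) else x
  filt <- wavelet_filters(config$wavelet)
  details <- vector("list", k)
  a <- work
  for (j in seq_len(k)) {
    s <- 2L^(j - 1L)
    details[[j]] <- .acorr(a, filt$g, s)
    a <- .acorr(a, filt$h, s)
  }
  structure(list(details = details, approximation = a, config = config,
                 n = n, n_ext = length(work)),
            class = "swt_coeffs")
}

#' @export
print.swt_coeffs <- function(x, ...) {
  cat(sprintf("swt_coeffs: %d level(s), n = %d (%s, %s boundary)\n",
              x$config$levels, x$n, x$config$wavelet, x$config$boundary))
  invisible(x)
}

.check_coeffs <- function(coeffs) {
  if (!inherits(coeffs, "swt_coeffs")) stop("expected an swt_coeffs object")
  k <- coeffs$config$levels
  if (length(coeffs$details) != k) {
    stop("coefficient object has ", length(coeffs$details),
         " detail arrays but config declares ", k, " levels")
  }
  lens <- c(vapply(coeffs$details, length, integer(1)),
            length(coeffs$approximation))
  if (any(lens != coeffs$n_ext)) {
    stop("inconsistent coefficient array lengths: ",
         paste(lens, collapse = ", "))
  }
  invisible(TRUE)
}

#' Inverse stationary wavelet transform
#'
#' Exact inverse of [swt_decompose()]. Each level is inverted by
#' circular convolution of the approximation and detail arrays with the
#' analysis filters and halving -- the average of the two redundant
#' polyphase branches. Linear in the coefficients, so reconstructing
#' approximation and details separately and summing reproduces the
#' signal too.
#'
#' @param coeffs An `swt_coeffs` object (arrays may be modified, e.g.
#'   thresholded, but must keep consistent lengths).
#' @return Numeric vector of length `coeffs$n`.
#' @export
swt_reconstruct <- function(coeffs) {
  .check_coeffs(coeffs)
  filt <- wavelet_filters(coeffs$config$wavelet)
  a <- coeffs$approximation
  for (j in rev(seq_len(coeffs$config$levels))) {
    s <- 2L^(j - 1L)
    a <- 0.5 * (.aconv(a, filt$h, s) + .aconv(coeffs$details[[j]], filt$g, s))
  }
  a[seq_len(coeffs$n)]
}

#' Per-level energy distribution of wavelet coefficients
#'
#' Shares of the total coefficient energy held by each detail level and
#' the final approximation, with the nominal dyadic frequency band each
#' level represents. Detail level `i` nominally covers
#' `[fs/2^(i+1), fs/2^i]` Hz and the approximation `[0, fs/2^(k+1)]`.
#' The bands are ideal labels: real filters overlap, so a narrowband
#' tone near an edge spreads into neighbouring levels.
#'
#' @param coeffs An `swt_coeffs` object with nonzero total energy.
#' @param fs Sampling rate in Hz.
#' @return A data.frame with columns `level` (`"d1" .. "dk"`, `"a<k>"`),
#'   `f_low`, `f_high` (Hz) and `energy_pct` summing to 100.
#' @export
energy_distribution <- function(coeffs, fs) {
  .check_coeffs(coeffs)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  k <- coeffs$config$levels
  e <- c(vapply(coeffs$details, function(d) sum(d^2), numeric(1)),
         sum(coeffs$approximation^2))
  tot <- sum(e)
  if (tot <= 0) stop("zero-energy coefficients: energy shares undefined")
  data.frame(
    level = c(paste0("d", seq_len(k)), paste0("a", k)),
    f_low = c(fs / 2^(seq_len(k) + 1), 0),
    f_high = c(fs / 2^seq_len(k), fs / 2^(k + 1)),
    energy_pct = 100 * e / tot
  )
}
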