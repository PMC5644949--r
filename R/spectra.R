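#' Construct an epoch-by-frequency power spectral density object
#'
#' Holds one power spectrum per scoring epoch on a 0.25-Hz frequency
#' axis, row-aligned with a hypnogram.
#'
#' @param psd Numeric matrix, epochs x frequency bins, non-negative
#'   power density (consistent units, e.g. uV^2/Hz).
#' @param freq Numeric vector of bin-center frequencies in Hz, spaced
#'   exactly 0.25 Hz.
#' @return An object of class `"spectra"`.
#' @export
spectra <- function(psd, freq) {
  psd <- as.matrix(psd)
  freq <- as.numeric(freq)
  validate_spectra(structure(
    list(freq = freq, psd = psd),
    class = "spectra"
  ))
}

validate_spectra <- function(x) {
  stopifnot(inherits(x, "spectra"))
  if (length(x$freq) != ncol(x$psd)) {
    stop("frequency axis length must match psd column count", call. = FALSE)
  }
  if (length(x$freq) > 1) {
    dfreq <- diff(x$freq)
    if (max(abs(dfreq - 0.25)) > 1e-9) {
      stop("frequency bin spacing must be exactly 0.25 Hz", call. = FALSE)
    }
  }
  if (any(x$psd < 0)) stop("power density must be non-negative", call. = FALSE)
  x
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf(
    "<spectra> %d epochs x %d bins (%.2f-%.2f Hz, 0.25 Hz spacing)\n",
    nrow(x$psd), length(x$freq), min(x$freq), max(x$freq)
  ))
  invisible(x)
}

#' @export
dim.spectra <- function(x) dim(x$psd)

# Column indices of bin centers with lo <= f <= hi (band closed on both
# edges).
band_bins <- function(freq, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < min(freq) - 1e-9 || band[2] > max(freq) + 1e-9) {
    stop(sprintf(
      "band %g-%g Hz lies outside the frequency axis (%g-%g Hz)",
      band[1], band[2], min(freq), max(freq)
    ), call. = FALSE)
  }
  which(freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9)
}

#' Integrated band power
#'
#' Sums power density over all frequency bins whose center lies in the
#' closed band `[lo, hi]` and multiplies by the 0.25 Hz bin width, i.e. a
#' rectangle-rule integral of the PSD over the band.
#'
#' Canonical bands: mouse NREM delta 0.75-4 Hz; human slow-wave activity
#' 0.5-4.5 Hz; slow oscillation 0.25-1.0 Hz.
#'
#' @param x A [spectra()] object or a single numeric PSD row.
#' @param band Numeric length-2 vector `c(lo, hi)` in Hz; both edges
#'   must be multiples of 0.25.
#' @param freq Frequency axis, required when `x` is a bare vector.
#' @return Numeric vector of band power, one value per epoch (or a
#'   scalar for a single row).
#' @export
#' @examples
#' band_power(rep(2, 196), c(0.75, 4), freq = seq(0.25, 49, 0.25))
band_power <- function(x, band, freq = NULL) {
  if (inherits(x, "spectra")) {
    freq <- x$freq
    mat <- x$psd
  } else {
    if (is.null(freq)) stop("freq required for a bare PSD vector", call. = FALSE)
    mat <- matrix(x, nrow = 1)
  }
  if (any(abs(band / 0.25 - round(band / 0.25)) > 1e-9)) {
    stop("band edges must be multiples of 0.25 Hz", call. = FALSE)
  }
  idx <- band_bins(freq, band)
  out <- rowSums(mat[, idx, drop = FALSE]) * 0.25
  as.numeric(out)
}

#' Average spectra over blocks of consecutive epochs
#'
#' Human spectral analysis computes 4-s spectra and averages them over
#' five consecutive epochs to match the 20-s scoring epochs. Any trailing
#' remainder of fewer than `k` epochs is dropped with a warning.
#'
#' @param x A [spectra()] object.
#' @param k Block size (number of consecutive epochs per average).
#' @return A [spectra()] object with `floor(n/k)` rows.
#' @export
average_blocks <- function(x, k = 5) {
  stopifnot(inherits(x, "spectra"), k >= 1)
  n <- nrow(x$psd)
  m <- n %/% k
  if (m == 0L) stop("fewer epochs than one block", call. = FALSE)
  if (n %% k != 0L) {
    warning(sprintf("dropping %d trailing epoch(s) not filling a block", n %% k))
  }
  idx <- rep(seq_len(m), each = k)
  avg <- rowsum(x$psd[seq_len(m * k), , drop = FALSE], idx) / k
  dimnames(avg) <- NULL
  spectra(avg, x$freq)
}

#' Hann-taper power spectral density of epoched EEG
#'
#' Computes a one-sided periodogram per 4-s epoch with a single Hann
#' taper (no within-epoch averaging), yielding the 0.25 Hz frequency
#' resolution used for both mouse (200 Hz sampling) and human (256 Hz)
#' recordings. The DC bin is dropped; bins run from 0.25 Hz up to
#' `max_hz`.
#'
#' @param x Numeric matrix of epoched signal, epochs x samples, or a
#'   single-epoch numeric vector. Each epoch must span 4 s (`4 * fs`
#'   samples).
#' @param fs Sampling frequency in Hz (200 or 256).
#' @param max_hz Upper frequency bound of the returned axis; defaults to
#'   the Nyquist frequency.
#' @return A [spectra()] object in units of `x^2`/Hz.
#' @export
compute_psd <- function(x, fs = c(200, 256), max_hz = NULL) {
  fs <- match.arg(as.character(fs[1]), c("200", "256"))
  fs <- as.numeric(fs)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n != 4 * fs) {
    stop(sprintf(
      "epoch length is %d samples; 4-s epochs at %g Hz require %d",
      n, fs, 4 * fs
    ), call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n) # periodic Hann taper
  xw <- sweep(x, 2, w, `*`)
  ft <- t(stats::mvfft(t(xw)))
  # one-sided PSD: P(f) = 2 |X|^2 / (fs * sum(w^2)); Nyquist not doubled
  scale <- 1 / (fs * sum(w^2))
  nhalf <- n %/% 2
  p <- Mod(ft[, 2:(nhalf + 1), drop = FALSE])^2 * scale
  p[, -nhalf] <- 2 * p[, -nhalf, drop = FALSE]
  freq <- seq_len(nhalf) * fs / n
  if (is.null(max_hz)) max_hz <- fs / 2
  keep <- freq <= max_hz + 1e-9
  spectra(p[, keep, drop = FALSE], freq[keep])
}
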