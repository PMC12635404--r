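# Synthetic spectrum rendering and reduction of spectrum series to traces.
#
# Peaks are Lorentzian; a doublet from one-bond 13C-13C coupling contributes
# two half-amplitude components at center +/- J/2 (in Hz). Windows are
# half-open ppm intervals [low, high) so adjacent windows partition cleanly.

#' Convert a frequency offset in Hz to ppm (and back)
#'
#' @param hz,ppm Offset values.
#' @param freq_MHz Spectrometer frequency in the observed nucleus frame, MHz.
#' @return The converted offset.
#' @export
hz_to_ppm <- function(hz, freq_MHz) {
  stopifnot(freq_MHz > 0)
  hz / freq_MHz
}

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, freq_MHz) {
  stopifnot(freq_MHz > 0)
  ppm * freq_MHz
}

#' Define a spectral peak and its integration window
#'
#' @param name Peak/metabolite name.
#' @param center_ppm Chemical shift of the multiplet center, ppm.
#' @param window_ppm Length-2 numeric `(low, high)`: the half-open ppm
#'   interval `[low, high)` used for integration; must contain the center.
#' @param multiplicity `"singlet"` or `"doublet"`.
#' @param J_Hz Scalar coupling constant in Hz (doublets only, `> 0`).
#' @param linewidth_Hz Full width at half maximum, Hz, `> 0`.
#' @param amplitude Peak amplitude in arbitrary units (generation only);
#'   the rendered multiplet maximum for a well-resolved singlet equals
#'   `amplitude`, a doublet splits it into two half-amplitude components.
#' @return An object of class `peak_definition`.
#' @export
peak_definition <- function(name, center_ppm, window_ppm,
                            multiplicity = c("singlet", "doublet"),
                            J_Hz = NULL, linewidth_Hz = 2, amplitude = 1) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(length(window_ppm) == 2L, is.numeric(window_ppm))
  window_ppm <- sort(as.numeric(window_ppm))
  if (center_ppm < window_ppm[1] || center_ppm >= window_ppm[2])
    stop("window must contain the peak center: ", name)
  if (multiplicity == "doublet") {
    if (is.null(J_Hz) || J_Hz <= 0) stop("doublet requires J_Hz > 0: ", name)
  }
  if (linewidth_Hz <= 0) stop("linewidth_Hz must be > 0")
  structure(
    list(name = name, center_ppm = center_ppm, window_ppm = window_ppm,
         multiplicity = multiplicity, J_Hz = J_Hz,
         linewidth_Hz = linewidth_Hz, amplitude = amplitude),
    class = "peak_definition"
  )
}

# Lorentzian component positions (ppm) and amplitudes for one peak
.peak_components <- function(peak, freq_MHz) {
  if (peak$multiplicity == "doublet") {
    off <- hz_to_ppm(peak$J_Hz / 2, freq_MHz)
    list(center = peak$center_ppm + c(-off, off),
         amplitude = rep(peak$amplitude / 2, 2))
  } else {
    list(center = peak$center_ppm, amplitude = peak$amplitude)
  }
}

#' Render a one-dimensional spectrum from peak definitions
#'
#' Sum of Lorentzian lines, each with unit-normalized shape
#' `A * (hw^2 / ((x - x0)^2 + hw^2))` where `hw` is the half width at half
#' maximum, plus optional additive Gaussian noise.
#'
#' @param peaks A list of [peak_definition()] objects (a single one is
#'   accepted).
#' @param axis ppm axis (strictly monotonic; descending by NMR convention).
#' @param freq_MHz Spectrometer frequency, MHz (Hz-to-ppm conversion of J and
#'   linewidths).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = none).
#' @param seed Optional integer seed making the noise reproducible.
#' @return Numeric intensity vector along `axis`.
#' @export
synthesize_spectrum <- function(peaks, axis, freq_MHz, noise_sd = 0,
                                seed = NULL) {
  if (inherits(peaks, "peak_definition")) peaks <- list(peaks)
  stopifnot(length(axis) >= 2, all(is.finite(axis)))
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotonic")
  rng <- range(axis)
  for (pk in peaks) {
    if (pk$window_ppm[1] < rng[1] || pk$window_ppm[2] > rng[2])
      stop("axis does not cover the window of peak ", pk$name)
  }
  y <- numeric(length(axis))
  for (pk in peaks) {
    comp <- .peak_components(pk, freq_MHz)
    hw <- hz_to_ppm(pk$linewidth_Hz, freq_MHz) / 2
    for (j in seq_along(comp$center)) {
      y <- y + comp$amplitude[j] * hw^2 /
        ((axis - comp$center[j])^2 + hw^2)
    }
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(axis), sd = noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(axis), sd = noise_sd))
    }
    y <- y + noise
  }
  y
}

#' A series of spectra over scans
#'
#' @param ppm_axis Strictly monotonic ppm axis (descending by convention).
#' @param intensities Matrix, scans in rows, axis points in columns.
#' @param freq_MHz Spectrometer frequency, MHz, `> 0`.
#' @param scan_times_s Scan time stamps, seconds, one per row.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(ppm_axis, intensities, freq_MHz, scan_times_s) {
  intensities <- as.matrix(intensities)
  d <- diff(ppm_axis)
  if (!(all(d > 0) || all(d < 0))) stop("ppm_axis must be strictly monotonic")
  if (ncol(intensities) != length(ppm_axis))
    stop("intensities must have one column per axis point")
  if (nrow(intensities) != length(scan_times_s))
    stop("intensities must have one row per scan time")
  if (freq_MHz <= 0) stop("freq_MHz must be > 0")
  structure(
    list(ppm_axis = as.numeric(ppm_axis), intensities = intensities,
         freq_MHz = freq_MHz, scan_times_s = as.numeric(scan_times_s)),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %d scans x %d points, %.6g..%.6g ppm @ %.4g MHz\n",
              nrow(x$intensities), length(x$ppm_axis),
              max(x$ppm_axis), min(x$ppm_axis), x$freq_MHz))
  invisible(x)
}

#' Default carbon-13 peak table for hyperpolarized glucose runs
#'
#' Reference chemical shifts of the species visible in summed spectra of a
#' hyperpolarized [U-13C,2H]glucose experiment: [2-13C]pyruvate at 208 ppm,
#' [1-13C]lactate at 183.5 ppm (doublet, one-bond C-C coupling 55 Hz),
#' pyruvate hydrate at 172 ppm, bicarbonate at 162 ppm, and the glucose
#' anomeric region integrated over 92-98 ppm. All windows and shifts are
#' conventions, overridable by constructing [peak_definition()]s directly.
#'
#' @return Named list of [peak_definition()] objects.
#' @export
default_c13_peaks <- function() {
  list(
    pyruvate_c2 = peak_definition("pyruvate_c2", 208, c(206, 210),
                                  linewidth_Hz = 8),
    lactate = peak_definition("lactate", 183.5, c(181, 186),
                              multiplicity = "doublet", J_Hz = 55,
                              linewidth_Hz = 8),
    pyruvate_hydrate = peak_definition("pyruvate_hydrate", 172,
                                       c(170.5, 173.5), linewidth_Hz = 8),
    bicarbonate = peak_definition("bicarbonate", 162, c(160, 164),
                                  linewidth_Hz = 8),
    glucose = peak_definition("glucose", 95, c(92, 98), linewidth_Hz = 15)
  )
}

# indices of axis points falling in the half-open window [low, high)
.window_idx <- function(axis, window) {
  which(axis >= window[1] & axis < window[2])
}

#' Trapezoidal integration of a spectral window
#'
#' Integrates intensity over the half-open ppm window `[low, high)`, with an
#' optional linear baseline anchored at the window edges subtracted first.
#'
#' @param spectrum Intensity vector.
#' @param axis ppm axis matching `spectrum`.
#' @param window Length-2 numeric `(low, high)` ppm.
#' @param baseline If `TRUE`, subtract a straight line anchored at the
#'   window edges before integrating. Each anchor is the mean of up to 5
#'   edge points (at most a tenth of the window), which keeps the anchor
#'   stable on noisy spectra.
#' @return The integral (intensity x ppm).
#' @export
integrate_peak <- function(spectrum, axis, window, baseline = FALSE) {
  stopifnot(length(spectrum) == length(axis), length(window) == 2L)
  window <- sort(window)
  if (window[1] < min(axis) || window[2] > max(axis) + 1e-12)
    stop("window outside ppm axis")
  idx <- .window_idx(axis, window)
  if (length(idx) < 2L) stop("empty integration window")
  x <- axis[idx]; y <- spectrum[idx]
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (baseline) {
    n <- length(x)
    m <- max(1L, min(5L, n %/% 10))
    x_lo <- mean(x[seq_len(m)]); y_lo <- mean(y[seq_len(m)])
    x_hi <- mean(x[n - seq_len(m) + 1L]); y_hi <- mean(y[n - seq_len(m) + 1L])
    slope <- (y_hi - y_lo) / (x_hi - x_lo)
    y <- y - (y_lo + slope * (x - x_lo))
  }
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Reduce a spectrum series to substrate/product dynamic traces
#'
#' Integrates the substrate and product windows in every scan and attaches
#' the scan times, yielding the [dynamic_series()] consumed by
#' [fit_two_pool()].
#'
#' @param spectra A [spectrum_series()].
#' @param substrate_peak,product_peak [peak_definition()] objects whose
#'   windows select the two pools.
#' @param baseline Passed to [integrate_peak()].
#' @return A [dynamic_series()]; if the two windows overlap a warning is
#'   issued and recorded in the `"provenance"` attribute.
#' @export
series_to_dynamic <- function(spectra, substrate_peak, product_peak,
                              baseline = FALSE) {
  stopifnot(inherits(spectra, "spectrum_series"),
            inherits(substrate_peak, "peak_definition"),
            inherits(product_peak, "peak_definition"))
  prov <- character(0)
  ws <- substrate_peak$window_ppm; wp <- product_peak$window_ppm
  if (ws[1] < wp[2] && wp[1] < ws[2]) {
    msg <- sprintf("integration windows overlap: %s [%g,%g) and %s [%g,%g)",
                   substrate_peak$name, ws[1], ws[2],
                   product_peak$name, wp[1], wp[2])
    warning(msg)
    prov <- c(prov, msg)
  }
  n <- nrow(spectra$intensities)
  S <- numeric(n); P <- numeric(n)
  for (i in seq_len(n)) {
    S[i] <- integrate_peak(spectra$intensities[i, ], spectra$ppm_axis, ws,
                           baseline = baseline)
    P[i] <- integrate_peak(spectra$intensities[i, ], spectra$ppm_axis, wp,
                           baseline = baseline)
  }
  out <- dynamic_series(spectra$scan_times_s, S, P,
                        labels = c(substrate = substrate_peak$name,
                                   product = product_peak$name))
  attr(out, "provenance") <- prov
  out
}

#' Robust noise estimate from a signal-free region
#'
#' Estimates the spectral noise standard deviation as the scaled median
#' absolute deviation (1.4826 x MAD) of the intensities in a window known to
#' contain no signal; insensitive to baseline offset.
#'
#' @param spectrum Intensity vector.
#' @param axis Matching ppm axis.
#' @param signal_free_window Length-2 numeric `(low, high)` ppm containing at
#'   least 16 axis points.
#' @param peaks Optional list of [peak_definition()]; if any peak window
#'   overlaps the noise window the call is rejected.
#' @return Noise standard deviation estimate.
#' @export
estimate_noise <- function(spectrum, axis, signal_free_window, peaks = NULL) {
  stopifnot(length(spectrum) == length(axis))
  w <- sort(signal_free_window)
  if (!is.null(peaks)) {
    if (inherits(peaks, "peak_definition")) peaks <- list(peaks)
    for (pk in peaks) {
      if (w[1] < pk$window_ppm[2] && pk$window_ppm[1] < w[2])
        stop("signal-free window overlaps peak ", pk$name)
    }
  }
  idx <- .window_idx(axis, w)
  if (length(idx) < 16L)
    stop("signal-free window must contain at least 16 points, has ",
         length(idx))
  stats::mad(spectrum[idx])
}
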