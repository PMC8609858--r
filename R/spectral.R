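#' Emission spectrum container
#'
#' A two-column table of wavelength (nm, strictly increasing) and spectral
#' photon flux density per nm (non-negative). This is the raw input from which
#' the chlorophyll fluorescence band around 685 nm is located and integrated
#' into a single photon flux density.
#'
#' @param wavelength_nm strictly increasing numeric grid, nm.
#' @param intensity non-negative spectral intensity on the same grid.
#' @return A data frame of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity) {
  if (!is.numeric(wavelength_nm) || !is.numeric(intensity) ||
      length(wavelength_nm) != length(intensity) ||
      length(wavelength_nm) < 2L) {
    stop("wavelength and intensity must be numeric vectors of equal length >= 2",
         call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("`intensity` must be finite and non-negative", call. = FALSE)
  }
  structure(
    data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
    class = c("emission_spectrum", "data.frame")
  )
}

# linear baseline through the intensities interpolated at the interval edges
linear_baseline <- function(spec, interval) {
  lo <- stats::approx(spec$wavelength_nm, spec$intensity,
                      xout = interval[1])$y
  hi <- stats::approx(spec$wavelength_nm, spec$intensity,
                      xout = interval[2])$y
  function(wl) lo + (hi - lo) * (wl - interval[1]) / diff(interval)
}

check_interval <- function(spec, interval, name) {
  if (!is.numeric(interval) || length(interval) != 2L ||
      interval[1] >= interval[2]) {
    stop(sprintf("`%s` must be an increasing (lo, hi) pair", name),
         call. = FALSE)
  }
  rng <- range(spec$wavelength_nm)
  if (interval[1] < rng[1] || interval[2] > rng[2]) {
    stop(sprintf("`%s` [%g, %g] nm lies outside the spectral grid [%g, %g] nm",
                 name, interval[1], interval[2], rng[1], rng[2]),
         call. = FALSE)
  }
}

#' Locate the chlorophyll fluorescence peak
#'
#' Returns the wavelength of maximum baseline-corrected intensity inside the
#' search window. The baseline is the straight line through the window-edge
#' intensities, so a smooth scattered-light background does not pull the
#' maximum. Ties (including the all-flat case) resolve toward the lower
#' wavelength; a spectrum with no intensity above the baseline is reported as
#' having no distinct peak.
#'
#' @param spec an [emission_spectrum()].
#' @param search_window numeric `(lo, hi)` in nm, inside the grid; default
#'   `c(670, 700)`, bracketing the ~685 nm chlorophyll emission.
#' @return A list with `wavelength_nm` (the peak position) and `distinct`
#'   (`FALSE` when nothing rises above the baseline).
#' @examples
#' sim <- make_spectrum(seed = 1)
#' detect_fluorescence_peak(sim$spectrum)$wavelength_nm   # ~685
#' @export
detect_fluorescence_peak <- function(spec, search_window = c(670, 700)) {
  stopifnot(inherits(spec, "emission_spectrum"))
  check_interval(spec, search_window, "search_window")
  inside <- spec$wavelength_nm >= search_window[1] &
    spec$wavelength_nm <= search_window[2]
  if (!any(inside)) {
    stop("`search_window` contains no grid points", call. = FALSE)
  }
  wl <- spec$wavelength_nm[inside]
  corrected <- pmax(spec$intensity[inside] - linear_baseline(spec, search_window)(wl), 0)
  if (max(corrected) <= 0) {
    return(list(wavelength_nm = wl[1], distinct = FALSE))
  }
  list(wavelength_nm = wl[which.max(corrected)], distinct = TRUE)
}

#' Band-integrated photon flux density
#'
#' Integrates the baseline-corrected spectral intensity over a wavelength band
#' with the trapezoidal rule on the native grid (plus interpolated values at
#' the exact band edges). With `baseline = "linear"` the straight line through
#' the band-edge intensities is subtracted first and negative corrected values
#' are clipped to zero; `baseline = "none"` integrates the raw intensity. The
#' result is the chlorophyll fluorescence photon flux density (CFPFD) that
#' feeds [calibrate_per_cell_flux()].
#'
#' @param spec an [emission_spectrum()].
#' @param band numeric `(lo, hi)` in nm, inside the grid; default
#'   `c(670, 700)`.
#' @param baseline `"linear"` (endpoint baseline, the default) or `"none"`.
#' @return Integrated photon flux density in the intensity unit times nm
#'   (umol photons/m^2/s when the spectrum is calibrated per nm).
#' @export
band_integrated_cfpfd <- function(spec, band = c(670, 700),
                                  baseline = c("linear", "none")) {
  stopifnot(inherits(spec, "emission_spectrum"))
  baseline <- match.arg(baseline)
  check_interval(spec, band, "band")
  inside <- spec$wavelength_nm > band[1] & spec$wavelength_nm < band[2]
  wl <- c(band[1], spec$wavelength_nm[inside], band[2])
  intens <- c(
    stats::approx(spec$wavelength_nm, spec$intensity, xout = band[1])$y,
    spec$intensity[inside],
    stats::approx(spec$wavelength_nm, spec$intensity, xout = band[2])$y
  )
  if (baseline == "linear") {
    intens <- pmax(intens - linear_baseline(spec, band)(wl), 0)
  }
  pracma::trapz(wl, intens)
}

#' Read and write emission spectra as CSV
#'
#' Plain CSV with mandatory header `wavelength_nm,intensity`; lines starting
#' with `#` are skipped. The reader validates the spectrum invariants, so a
#' non-monotone wavelength grid is rejected rather than silently accepted.
#'
#' @param path file path.
#' @return `read_spectrum_csv()` returns an [emission_spectrum()];
#'   `write_spectrum_csv()` invisibly returns `path`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    stop("spectrum CSV must have columns `wavelength_nm` and `intensity`",
         call. = FALSE)
  }
  emission_spectrum(df$wavelength_nm, df$intensity)
}

#' @rdname read_spectrum_csv
#' @param spec an [emission_spectrum()] to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "emission_spectrum"))
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}
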