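#' Physical parameters of the fluorescence propagation model
#'
#' Bundles the three constants the photon-flux model depends on: the plastid
#' radius `r` (the emitting/receiving cross-section of a cell), the diffuse
#' attenuation coefficient of light underwater `Kd` (Beer-Lambert decay of the
#' ~685 nm fluorescence band), and the chlorophyll fluorescence photon flux
#' (CFPF) emitted by a single cell `u`. The defaults are the parameter set used
#' throughout the bloom-scale calculations: r = 3 um, Kd = 0.57 per metre, and
#' u = 9.07e-12 umol photons per second — the value obtained by
#' [calibrate_per_cell_flux()] from the bulk culture measurement.
#'
#' @param plastid_radius plastid radius in metres (default `3e-6`).
#' @param attenuation_kd diffuse attenuation coefficient in 1/m (default
#'   `0.57`).
#' @param per_cell_flux CFPF emitted per cell, umol photons/s (default
#'   `9.07e-12`).
#' @return An object of class `optical_params`.
#' @seealso [calibrate_per_cell_flux()] to derive `per_cell_flux` from a
#'   measured bulk photon flux density.
#' @examples
#' optical_params()
#' optical_params(plastid_radius = micrometres(3))
#' @export
optical_params <- function(plastid_radius = 3e-6,
                           attenuation_kd = 0.57,
                           per_cell_flux = 9.07e-12) {
  assert_positive(plastid_radius, "plastid_radius")
  assert_positive(attenuation_kd, "attenuation_kd")
  assert_positive(per_cell_flux, "per_cell_flux")
  structure(
    list(plastid_radius = plastid_radius,
         attenuation_kd = attenuation_kd,
         per_cell_flux = per_cell_flux),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat("Optical parameters of the fluorescence model\n")
  cat(sprintf("  plastid radius r : %g m\n", x$plastid_radius))
  cat(sprintf("  attenuation Kd   : %g 1/m\n", x$attenuation_kd))
  cat(sprintf("  per-cell flux u  : %g umol photons/s\n", x$per_cell_flux))
  invisible(x)
}

#' Bulk fluorescence measurement used to calibrate the per-cell flux
#'
#' Describes a laboratory measurement of the chlorophyll fluorescence photon
#' flux density (CFPFD) emitted by a known volume of culture at a known cell
#' density. The sample is modelled as a cube observed through one face;
#' isotropic emission means one sixth of all emitted photons leave through the
#' observed face, hence the default `geometry_factor = 6` when inverting the
#' measurement to a per-cell flux.
#'
#' @param measured_cfpfd measured photon flux density, umol photons/m^2/s.
#' @param cell_density cell density in cells per cubic metre (use
#'   [cells_per_ml()] for laboratory units).
#' @param sample_volume sample volume in cubic metres (default `1e-6`, i.e.
#'   1 mL).
#' @param geometry_factor reciprocal of the fraction of emitted photons that
#'   exit through the observed face (default 6 for a cube face under isotropic
#'   emission).
#' @return An object of class `calibration_measurement`.
#' @examples
#' calibration_measurement(2.418e-2, cells_per_ml(1.6e6))
#' @export
calibration_measurement <- function(measured_cfpfd,
                                    cell_density,
                                    sample_volume = 1e-6,
                                    geometry_factor = 6) {
  assert_non_negative(measured_cfpfd, "measured_cfpfd")
  assert_positive(cell_density, "cell_density")
  assert_positive(sample_volume, "sample_volume")
  assert_positive(geometry_factor, "geometry_factor")
  structure(
    list(measured_cfpfd = measured_cfpfd,
         cell_density = cell_density,
         sample_volume = sample_volume,
         geometry_factor = geometry_factor),
    class = "calibration_measurement"
  )
}

#' Per-cell emitted photon flux from a bulk measurement
#'
#' Converts a bulk chlorophyll fluorescence photon flux density into the CFPF
#' emitted by a single cell. The sample volume is treated as a cube observed
#' through one face of area `sample_volume^(2/3)`; the photons crossing that
#' face are `measured_cfpfd * face_area` per second, a `1/geometry_factor`
#' share of the total isotropic emission. Dividing the total emission by the
#' number of cells in the volume gives
#'
#' \deqn{u = g \cdot \mathrm{CFPFD} \cdot V^{2/3} / (N V)}
#'
#' With the reference measurement (2.418e-2 umol/m^2/s, 1 mL, 1.6e6 cells/mL,
#' g = 6) this yields u = 9.07e-12 umol photons/s.
#'
#' @param meas a [calibration_measurement()].
#' @return Per-cell photon flux `u` in umol photons/s.
#' @examples
#' meas <- calibration_measurement(2.418e-2, cells_per_ml(1.6e6))
#' calibrate_per_cell_flux(meas)
#' @export
calibrate_per_cell_flux <- function(meas) {
  stopifnot(inherits(meas, "calibration_measurement"))
  face_area <- meas$sample_volume^(2 / 3)
  total_cells <- meas$cell_density * meas$sample_volume
  meas$geometry_factor * meas$measured_cfpfd * face_area / total_cells
}

#' Re-predict the bulk photon flux density from a per-cell flux
#'
#' Inverse of [calibrate_per_cell_flux()]: given a per-cell flux and the
#' measurement geometry, predicts the CFPFD that would be observed through one
#' face of the sample cube. Used as a round-trip consistency check on the
#' calibration.
#'
#' @param per_cell_flux per-cell photon flux, umol photons/s.
#' @param meas a [calibration_measurement()] supplying the geometry (its
#'   `measured_cfpfd` is ignored).
#' @return Predicted photon flux density, umol photons/m^2/s.
#' @export
predict_bulk_cfpfd <- function(per_cell_flux, meas) {
  stopifnot(inherits(meas, "calibration_measurement"))
  assert_non_negative(per_cell_flux, "per_cell_flux")
  face_area <- meas$sample_volume^(2 / 3)
  total_cells <- meas$cell_density * meas$sample_volume
  per_cell_flux * total_cells / (meas$geometry_factor * face_area)
}
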