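#' Photon flux density received by one cell from a single neighbour
#'
#' Two-cell model: the emitting cell is treated as a point source of photon
#' flux `u`; the receiving plastid of radius `r` at centre-to-centre distance
#' `R` intercepts the solid-angle fraction `pi r^2 / (4 pi R^2)`, and the
#' intercepted flux is normalized by the illuminated half of a spherical
#' plastid surface, `S_plastid / 2 = 2 pi r^2`:
#'
#' \deqn{\mathrm{CFPFD} = u \frac{\pi r^2}{4\pi R^2} \Big/ (2\pi r^2)
#'   = \frac{u}{8 \pi R^2}}
#'
#' The plastid radius cancels, leaving a pure inverse-square law. No
#' attenuation term is applied: over micrometre separations
#' `exp(-Kd R) ~ 1` to better than 1e-5. "Adjacent" cells correspond to the
#' minimum centre distance `R = 2r` (touching, not overlapping), where the
#' model gives ~0.01 umol/m^2/s with the default parameters; at R = 100 um it
#' gives 3.61e-5.
#'
#' @param distance centre-to-centre distance `R` in metres; may be a vector.
#' @param params an [optical_params()] object.
#' @return Received photon flux density, umol photons/m^2/s.
#' @examples
#' pairwise_cfpfd(micrometres(6))    # touching cells, ~1e-2
#' pairwise_cfpfd(micrometres(100))  # ~3.61e-5
#' @export
pairwise_cfpfd <- function(distance, params = optical_params()) {
  stopifnot(inherits(params, "optical_params"), is.numeric(distance))
  if (any(!is.finite(distance))) {
    stop("`distance` must be finite", call. = FALSE)
  }
  if (any(distance < 2 * params$plastid_radius)) {
    stop(sprintf(
      "centre distance below 2r = %g m: cells would overlap (point-source singularity at R = 0)",
      2 * params$plastid_radius), call. = FALSE)
  }
  params$per_cell_flux / (8 * pi * distance^2)
}

#' Population photon flux: closed form of the attenuated mean-field integral
#'
#' In an evenly distributed population of density `N`, the shell at distance
#' `R` contributes `4 pi R^2 dR * N` point sources, each delivering
#' `u * pi r^2 / (4 pi R^2)` to the focal cell, attenuated by
#' `exp(-Kd R)`. Integrating over all space:
#'
#' \deqn{\mathrm{CFPF} = \int_0^\infty 4\pi R^2 N u \frac{\pi r^2}{4\pi R^2}
#'   e^{-K_d R}\, dR = \frac{N u \pi r^2}{K_d}}
#'
#' @param cell_density cells per cubic metre (vectorized).
#' @param params an [optical_params()] object.
#' @return Received photon flux, umol photons/s.
#' @seealso [population_cfpf_numeric()] for finite truncation radii,
#'   [population_cfpfd()] for the flux-density form.
#' @examples
#' population_cfpf_closed_form(cells_per_ml(1.6e6))
#' @export
population_cfpf_closed_form <- function(cell_density, params = optical_params()) {
  stopifnot(inherits(params, "optical_params"), is.numeric(cell_density))
  if (any(cell_density < 0)) {
    stop("`cell_density` must be non-negative", call. = FALSE)
  }
  cell_density * params$per_cell_flux * pi * params$plastid_radius^2 /
    params$attenuation_kd
}

#' Population photon flux by adaptive quadrature
#'
#' Numerically integrates the radially reduced integrand
#' `N u pi r^2 exp(-Kd R)` between `lower` and `truncation`. For an infinite
#' upper limit this must agree with [population_cfpf_closed_form()] to high
#' relative accuracy; for a finite limit the analytic value is
#' `(N u pi r^2 / Kd) (exp(-Kd lower) - exp(-Kd Rmax))`.
#'
#' @param cell_density cells per cubic metre (scalar).
#' @param params an [optical_params()] object.
#' @param truncation upper integration limit in metres, possibly `Inf`.
#' @param lower lower integration limit in metres (default 0, as in the
#'   mean-field model; harmless there because the R^2 shell volume cancels the
#'   inverse-square decay).
#' @param rel_tol,abs_tol quadrature tolerances passed to [stats::integrate()].
#' @return Received photon flux, umol photons/s.
#' @export
population_cfpf_numeric <- function(cell_density, params = optical_params(),
                                    truncation = Inf, lower = 0,
                                    rel_tol = 1e-10, abs_tol = 1e-12) {
  stopifnot(inherits(params, "optical_params"))
  assert_non_negative(cell_density, "cell_density")
  assert_non_negative(lower, "lower")
  if (!(is.numeric(truncation) && length(truncation) == 1L &&
        (is.infinite(truncation) || truncation > lower))) {
    stop("`truncation` must exceed `lower` (or be Inf)", call. = FALSE)
  }
  if (cell_density == 0) {
    return(0)
  }
  scale <- cell_density * params$per_cell_flux * pi * params$plastid_radius^2
  kd <- params$attenuation_kd
  res <- stats::integrate(function(R) exp(-kd * R), lower = lower,
                          upper = truncation,
                          rel.tol = rel_tol, abs.tol = abs_tol)
  if (res$message != "OK") {
    stop(sprintf("quadrature failed: %s (abs.error %g)",
                 res$message, res$abs.error), call. = FALSE)
  }
  scale * res$value
}

#' Population photon flux density at the focal cell
#'
#' Expresses the population CFPF as a flux density by dividing by the
#' illuminated half-surface of the plastid, `2 pi r^2`, mirroring the pairwise
#' normalization. In the infinite-space case the plastid radius cancels
#' algebraically:
#'
#' \deqn{\mathrm{CFPFD} = \frac{N u \pi r^2 / K_d}{2 \pi r^2}
#'   = \frac{N u}{2 K_d}}
#'
#' so the bloom-scale flux density depends only on cell density, per-cell flux
#' and attenuation.
#'
#' @inheritParams population_cfpf_numeric
#' @param truncation upper integration limit in metres; `Inf` (the default)
#'   uses the closed form.
#' @return Received photon flux density, umol photons/m^2/s.
#' @examples
#' population_cfpfd(cells_per_ml(1.6e6))   # ~12.7 umol/m^2/s
#' @export
population_cfpfd <- function(cell_density, params = optical_params(),
                             truncation = Inf) {
  stopifnot(inherits(params, "optical_params"))
  half_surface <- 2 * pi * params$plastid_radius^2
  if (length(cell_density) > 1L && is.infinite(truncation)) {
    return(population_cfpf_closed_form(cell_density, params) / half_surface)
  }
  if (is.infinite(truncation)) {
    population_cfpf_closed_form(cell_density, params) / half_surface
  } else {
    population_cfpf_numeric(cell_density, params, truncation) / half_surface
  }
}

#' Fraction of the population flux enclosed within a radius
#'
#' Under the attenuated mean-field integral, the share of the total CFPF
#' contributed by cells within radius `R` of the focal cell is
#' `1 - exp(-Kd R)`, independent of cell density and plastid radius.
#'
#' @param radius radius in metres (vectorized, non-negative).
#' @param params an [optical_params()] object.
#' @return Enclosed fraction in `[0, 1)`.
#' @export
enclosed_fraction <- function(radius, params = optical_params()) {
  stopifnot(inherits(params, "optical_params"), is.numeric(radius))
  if (any(radius < 0)) {
    stop("`radius` must be non-negative", call. = FALSE)
  }
  -expm1(-params$attenuation_kd * radius)
}

#' Radius enclosing a given fraction of the population flux
#'
#' Analytic inverse of [enclosed_fraction()]:
#' `R = -log(1 - fraction) / Kd`. For fraction 0.999 at Kd = 0.57/m this is
#' 12.12 m — the radius beyond which neighbouring cells contribute negligibly
#' to the received fluorescence, regardless of cell density.
#'
#' @param fraction target enclosed fraction, strictly inside (0, 1)
#'   (vectorized).
#' @param params an [optical_params()] object.
#' @return Radius in metres.
#' @examples
#' contribution_radius(0.999)  # ~12.12 m
#' @export
contribution_radius <- function(fraction, params = optical_params()) {
  stopifnot(inherits(params, "optical_params"), is.numeric(fraction))
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1)) {
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  -log1p(-fraction) / params$attenuation_kd
}

#' Received flux and flux density over a set of cell densities
#'
#' Evaluates the infinite-space population model at each density, emulating a
#' bloom-stage scan: the received CFPF is `N u pi r^2 / Kd` and the CFPFD is
#' `N u / (2 Kd)`, both linear in `N`.
#'
#' @param densities numeric vector of cell densities, cells per cubic metre,
#'   all non-negative.
#' @param params an [optical_params()] object.
#' @return A data frame with columns `cell_density`, `cfpf` (umol photons/s)
#'   and `cfpfd` (umol photons/m^2/s), one row per density.
#' @examples
#' density_scan(c(1e9, 3e11))  # bloom densities 1e6 and 3e8 cells/L
#' @export
density_scan <- function(densities, params = optical_params()) {
  stopifnot(inherits(params, "optical_params"), is.numeric(densities))
  if (length(densities) == 0L || any(!is.finite(densities)) ||
      any(densities < 0)) {
    stop("`densities` must be non-negative finite values", call. = FALSE)
  }
  data.frame(
    cell_density = densities,
    cfpf = population_cfpf_closed_form(densities, params),
    cfpfd = population_cfpf_closed_form(densities, params) /
      (2 * pi * params$plastid_radius^2)
  )
}
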