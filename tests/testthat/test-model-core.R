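# Per-cell flux calibration and the pairwise / population flux models.

reference_measurement <- function(...) {
  calibration_measurement(measured_cfpfd = 2.418e-2,
                          cell_density = cells_per_ml(1.6e6), ...)
}

test_that("calibration converts the bulk culture measurement to the per-cell flux", {
  u <- calibrate_per_cell_flux(reference_measurement())
  expect_equal(u, 9.07e-12, tolerance = 5e-3)
  # independent arithmetic: 6 * CFPFD * (1 cm)^2 face / (N * V) cells
  expect_equal(u, 6 * 2.418e-2 * 1e-4 / 1.6e6, tolerance = 1e-12)

  zero <- calibration_measurement(0, cells_per_ml(1.6e6))
  expect_identical(calibrate_per_cell_flux(zero), 0)

  doubled <- calibration_measurement(2.418e-2, cells_per_ml(3.2e6))
  expect_equal(calibrate_per_cell_flux(doubled), 4.534e-12, tolerance = 1e-3)
})

test_that("calibration rejects non-positive density and volume", {
  expect_error(calibration_measurement(1e-2, 0), "cell_density")
  expect_error(calibration_measurement(1e-2, -1), "cell_density")
  expect_error(calibration_measurement(1e-2, 1e12, sample_volume = 0),
               "sample_volume")
  expect_error(calibration_measurement(-1, 1e12), "measured_cfpfd")
})

test_that("calibration round-trips: re-predicting the bulk CFPFD recovers the input", {
  meas <- reference_measurement()
  u <- calibrate_per_cell_flux(meas)
  expect_equal(predict_bulk_cfpfd(u, meas), meas$measured_cfpfd,
               tolerance = 1e-12)
})

test_that("pairwise model reproduces the adjacency and 100 um flux densities", {
  expect_equal(pairwise_cfpfd(micrometres(6)), 1.0e-2, tolerance = 1e-2)
  expect_equal(pairwise_cfpfd(micrometres(100)), 3.61e-5, tolerance = 5e-3)
  # inverse-square: 10x closer than 100 um -> 100x the flux density
  expect_equal(pairwise_cfpfd(micrometres(10)),
               100 * pairwise_cfpfd(micrometres(100)), tolerance = 1e-12)
})

test_that("pairwise model obeys the inverse-square law and rejects overlap", {
  distances <- micrometres(c(6, 10, 25, 100, 1000))
  products <- pairwise_cfpfd(distances) * distances^2
  expect_equal(max(products) / min(products) - 1, 0, tolerance = 1e-12)
  expect_true(all(diff(pairwise_cfpfd(distances)) < 0))

  expect_error(pairwise_cfpfd(micrometres(5)), "overlap")
  expect_error(pairwise_cfpfd(0), "overlap")
})

test_that("population closed form evaluates N u pi r^2 / Kd", {
  p <- optical_params()
  expect_equal(population_cfpf_closed_form(1.6e12, p),
               1.6e12 * 9.07e-12 * pi * (3e-6)^2 / 0.57, tolerance = 1e-12)
  expect_equal(population_cfpf_closed_form(1.6e12, p), 7.198e-10,
               tolerance = 1e-3)
  expect_identical(population_cfpf_closed_form(0, p), 0)
  halved_kd <- optical_params(attenuation_kd = 0.57 * 2)
  expect_equal(population_cfpf_closed_form(1e12, halved_kd),
               population_cfpf_closed_form(1e12, p) / 2, tolerance = 1e-12)
})

test_that("quadrature matches the analytic truncated integral", {
  p <- optical_params()
  closed <- population_cfpf_closed_form(1.6e12, p)
  expect_equal(population_cfpf_numeric(1.6e12, p), closed, tolerance = 1e-6)
  # half-life truncation: Rmax = ln(2)/Kd encloses exactly half the flux
  expect_equal(population_cfpf_numeric(1.6e12, p, truncation = log(2) / 0.57),
               closed / 2, tolerance = 1e-6)
  expect_equal(population_cfpf_numeric(1.6e12, p, truncation = 12.119),
               closed * (1 - exp(-0.57 * 12.119)), tolerance = 1e-6)
})

test_that("truncated flux increases with radius and is bounded by the closed form", {
  p <- optical_params()
  closed <- population_cfpf_closed_form(1e10, p)
  radii <- c(0.5, 1, 2, 5, 10, 20)
  flux <- vapply(radii, function(rmax)
    population_cfpf_numeric(1e10, p, truncation = rmax), numeric(1))
  expect_true(all(diff(flux) > 0))
  expect_true(all(flux < closed))
  expect_equal(flux / closed, 1 - exp(-0.57 * radii), tolerance = 1e-6)
})

test_that("population flux density is N u / (2 Kd), independent of plastid radius", {
  expect_equal(population_cfpfd(1.6e12),
               1.6e12 * 9.07e-12 / (2 * 0.57), tolerance = 1e-12)
  base <- population_cfpfd(1e12, optical_params(plastid_radius = 3e-6))
  for (r_um in c(1, 10)) {
    expect_equal(population_cfpfd(1e12, optical_params(plastid_radius = micrometres(r_um))),
                 base, tolerance = 1e-12)
  }
  # density that would deliver the adjacency-level 0.01 umol/m^2/s
  n_inv <- 0.01 * 2 * 0.57 / 9.07e-12
  expect_equal(population_cfpfd(n_inv), 0.01, tolerance = 1e-12)
  expect_equal(n_inv, 1.257e9, tolerance = 1e-3)
})

test_that("contribution radius inverts the enclosed-fraction function", {
  p <- optical_params()
  expect_equal(contribution_radius(0.999, p), -log(0.001) / 0.57,
               tolerance = 1e-12)
  expect_equal(contribution_radius(0.5, p), log(2) / 0.57, tolerance = 1e-12)
  for (f in c(0.01, 0.25, 0.5, 0.9, 0.999, 0.999999)) {
    expect_equal(enclosed_fraction(contribution_radius(f, p), p), f,
                 tolerance = 1e-12)
  }
  expect_lt(contribution_radius(1e-9, p), 1e-8)
  expect_error(contribution_radius(0), "fraction")
  expect_error(contribution_radius(1), "fraction")
})

test_that("density scan is linear and monotone in cell density", {
  scan <- density_scan(c(0, 1e9, 3e11))
  expect_identical(scan$cfpfd[1], 0)
  expect_equal(scan$cfpfd[2], 0.008, tolerance = 1e-2)
  expect_equal(scan$cfpfd[3], 2.39, tolerance = 1e-2)
  expect_true(all(diff(scan$cfpfd) > 0))
  doubled <- density_scan(2 * c(1e9, 3e11))
  expect_equal(doubled$cfpfd, 2 * scan$cfpfd[-1], tolerance = 1e-12)
  expect_error(density_scan(c(1e9, -1)), "non-negative")
})

test_that("optical parameters reject non-positive values", {
  expect_error(optical_params(plastid_radius = 0), "plastid_radius")
  expect_error(optical_params(attenuation_kd = -0.5), "attenuation_kd")
  expect_error(optical_params(per_cell_flux = 0), "per_cell_flux")
})
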