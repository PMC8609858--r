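# Seeded generators: determinism and the statistical structure they promise.

test_that("all generators are deterministic under a fixed seed", {
  expect_identical(make_spectrum(seed = 4, noise_sd = 1e-5)$spectrum,
                   make_spectrum(seed = 4, noise_sd = 1e-5)$spectrum)
  expect_identical(make_pam_trace(seed = 4, noise_sd = 0.02),
                   make_pam_trace(seed = 4, noise_sd = 0.02))
  expect_identical(as.data.frame(make_station_table(seed = 4)),
                   as.data.frame(make_station_table(seed = 4)))
})

test_that("generated artifacts satisfy their consumers' invariants", {
  spec <- make_spectrum(seed = 8, noise_sd = 2e-5)$spectrum
  expect_s3_class(spec, "emission_spectrum")  # constructor enforces them
  rec <- make_pam_trace(seed = 8, noise_sd = 0.05)
  expect_s3_class(rec, "pam_record")
  expect_true(all(rec$steps$fm_prime <= rec$fm))
  tab <- make_station_table(seed = 8)
  expect_s3_class(tab, "station_table")
})

test_that("zero-amplitude spectra carry no band signal after baseline removal", {
  sim <- make_spectrum(seed = 3, peak_amplitude = 0)
  expect_lt(band_integrated_cfpfd(sim$spectrum), 1e-7)
  expect_identical(sim$peak_band_integral, 0)
  expect_false(detect_fluorescence_peak(sim$spectrum)$distinct)
})

test_that("the analytic peak integral matches the numeric band integration", {
  sim <- make_spectrum(seed = 6, peak_amplitude = 5e-3)
  expect_equal(band_integrated_cfpfd(sim$spectrum, band = sim$band),
               sim$peak_band_integral, tolerance = 1e-2)
})

test_that("zero quenching slope gives NPQ = 0 at every step", {
  rec <- make_pam_trace(seed = 1, npq_slope = 0)
  pars <- pam_parameters(rec)
  expect_equal(pars$npq, rep(0, nrow(pars)), tolerance = 1e-12)
})

test_that("PAM generator rejects invalid dark yields", {
  expect_error(make_pam_trace(f0 = 1.2, fm = 1.0), "exceed")
  expect_error(make_pam_trace(fm = 0), "fm")
  expect_error(make_pam_trace(par = c(-10, 50)), "non-negative")
})

test_that("station generator hits the per-bin correlation exactly in empirical mode", {
  rho <- c(0.85, 0.65, 0.45, 0)
  tab <- make_station_table(seed = 13, rho = rho)
  res <- stratified_pearson(tab)
  expect_equal(res$r[1:4], rho, tolerance = 1e-9)
})

test_that("population mode fluctuates around the target correlation", {
  rs <- vapply(1:200, function(s) {
    tab <- make_station_table(seed = s, bins = iron_bins(0.1, 0.3),
                              rho = 0.8, n_per_bin = 12, empirical = FALSE)
    stratified_pearson(tab, iron_bins(0.1, 0.3))$r[1]
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.05)
  expect_gt(sd(rs), 0)  # genuinely stochastic, unlike the empirical mode
})

test_that("a null correlation stays null on average", {
  rs <- vapply(1:200, function(s) {
    tab <- make_station_table(seed = 1000 + s, bins = iron_bins(0.1, 0.3),
                              rho = 0, n_per_bin = 50, empirical = FALSE)
    stratified_pearson(tab, iron_bins(0.1, 0.3))$r[1]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("generated iron values always fall inside their configured bin", {
  tab <- make_station_table(seed = 17)
  bins <- default_iron_bins()
  in_some_bin <- vapply(tab$iron, function(fe)
    any(fe >= bins$lower & fe <= bins$upper), logical(1))
  expect_true(all(in_some_bin))
})

test_that("station generator validates rho and bin counts", {
  expect_error(make_station_table(seed = 1, rho = c(1.2, 0, 0, 0)), "rho")
  expect_error(make_station_table(seed = 1, rho = c(0.5, 0.5)), "per iron bin")
  expect_error(make_station_table(seed = 1, n_per_bin = 2), "at least 3")
})
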