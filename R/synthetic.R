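#' Synthetic emission spectrum with a 685 nm fluorescence peak
#'
#' Generates an emission spectrum mimicking a blue-light-excited diatom
#' culture: a Gaussian chlorophyll fluorescence peak (default centre 685 nm,
#' sd 10 nm) riding on a smooth low-order polynomial scattered-light
#' background, with optional Gaussian measurement noise. The background is at
#' most quadratic so the linear-endpoint baseline removal used by
#' [band_integrated_cfpfd()] is nearly exact, keeping the analytic oracle
#' clean.
#'
#' The analytic band integral of the peak component (Gaussian area inside the
#' band minus the linear chord through the peak's own band-edge values — i.e.
#' what linear-endpoint baseline correction should recover) is returned
#' alongside. Supplying `target_band_integral` solves for the amplitude that
#' makes this analytic integral hit a required photon flux density, which is
#' how a spectrum reproducing the bulk calibration measurement is built.
#'
#' @param seed integer seed (mandatory determinism).
#' @param wavelength_nm wavelength grid, nm.
#' @param peak_centre,peak_sd Gaussian peak centre and standard deviation, nm.
#' @param peak_amplitude peak height in intensity units; ignored when
#'   `target_band_integral` is given.
#' @param target_band_integral optional photon flux density the peak's
#'   analytic band integral should equal.
#' @param background quadratic background coefficients `(b0, b1, b2)` in the
#'   scaled coordinate `t = (wl - min) / range`.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units; results are clipped at 0). Default 0.
#' @param band analysis band `(lo, hi)` in nm used for the analytic integral.
#' @return A list with `spectrum` (an [emission_spectrum()]),
#'   `peak_band_integral` (analytic, baseline-corrected), `peak_amplitude`
#'   and `band`.
#' @examples
#' sim <- make_spectrum(seed = 1, target_band_integral = 2.418e-2)
#' band_integrated_cfpfd(sim$spectrum)  # ~2.418e-2
#' @export
make_spectrum <- function(seed,
                          wavelength_nm = seq(450, 750, by = 0.5),
                          peak_centre = 685, peak_sd = 10,
                          peak_amplitude = 1e-3,
                          target_band_integral = NULL,
                          background = c(2e-4, -1.5e-4, 5e-5),
                          noise_sd = 0,
                          band = c(670, 700)) {
  assert_scalar(seed, "seed")
  assert_positive(peak_sd, "peak_sd")
  assert_non_negative(noise_sd, "noise_sd")
  if (length(background) != 3L || !is.numeric(background)) {
    stop("`background` must be three polynomial coefficients", call. = FALSE)
  }
  gauss <- function(wl, A) A * exp(-(wl - peak_centre)^2 / (2 * peak_sd^2))
  # analytic band integral of a unit-amplitude peak after linear-endpoint
  # baseline removal of the peak's own band-edge tails
  unit_area <- peak_sd * sqrt(2 * pi) *
    (stats::pnorm((band[2] - peak_centre) / peak_sd) -
       stats::pnorm((band[1] - peak_centre) / peak_sd)) -
    (gauss(band[1], 1) + gauss(band[2], 1)) / 2 * diff(band)
  if (!is.null(target_band_integral)) {
    assert_non_negative(target_band_integral, "target_band_integral")
    peak_amplitude <- target_band_integral / unit_area
  }
  assert_non_negative(peak_amplitude, "peak_amplitude")

  set.seed(seed)
  t <- (wavelength_nm - min(wavelength_nm)) / diff(range(wavelength_nm))
  bg <- background[1] + background[2] * t + background[3] * t^2
  if (any(bg < 0)) {
    stop("background polynomial must be non-negative on the grid",
         call. = FALSE)
  }
  intensity <- bg + gauss(wavelength_nm, peak_amplitude)
  if (noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sd)
  }
  list(
    spectrum = emission_spectrum(wavelength_nm, pmax(intensity, 0)),
    peak_band_integral = peak_amplitude * unit_area,
    peak_amplitude = peak_amplitude,
    band = band
  )
}

#' Synthetic PAM light curve
#'
#' Builds a light curve whose yields satisfy the [pam_record()] invariants by
#' construction: the light-adapted maximal yield quenches hyperbolically with
#' irradiance, `Fm'(PAR) = Fm / (1 + npq_slope * PAR)` (so
#' `NPQ = npq_slope * PAR`, non-decreasing), and the effective quantum yield
#' declines as `Y(II)(PAR) = (Fv/Fm) / (1 + y2_decay * PAR)`, with the
#' real-time yield recovered from `F = Fm' (1 - Y(II))`. At PAR = 0 the trace
#' reduces exactly to the dark-adapted state (`Fm' = Fm`, `F = F0`). The
#' default slopes give the qualitative light-response of a healthy
#' white-light-adapted diatom culture: Fv/Fm 0.6, Y(II) falling from 0.6
#' toward ~0.4 at 611 umol/m^2/s, NPQ rising to ~0.1.
#'
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param f0,fm dark-adapted yields, `fm >= f0 >= 0`.
#' @param par actinic irradiance steps, umol/m^2/s.
#' @param y2_decay hyperbolic decay rate of Y(II) with PAR, per (umol/m^2/s);
#'   0 gives a flat Y(II).
#' @param npq_slope linear NPQ accumulation rate with PAR; 0 gives no
#'   quenching (`Fm' = Fm` at every step).
#' @param noise_sd multiplicative log-normal noise sd on the yields; ordering
#'   invariants are re-imposed after jittering. Default 0.
#' @return A [pam_record()].
#' @export
make_pam_trace <- function(seed = 1, f0 = 0.4, fm = 1.0,
                           par = c(0, 86, 125, 190, 285, 420, 611),
                           y2_decay = 8.2e-4, npq_slope = 1.64e-4,
                           noise_sd = 0) {
  assert_scalar(seed, "seed")
  assert_non_negative(f0, "f0")
  assert_positive(fm, "fm")
  if (f0 > fm) {
    stop("`f0` must not exceed `fm`", call. = FALSE)
  }
  assert_non_negative(y2_decay, "y2_decay")
  assert_non_negative(npq_slope, "npq_slope")
  assert_non_negative(noise_sd, "noise_sd")
  if (any(par < 0)) {
    stop("`par` must be non-negative", call. = FALSE)
  }
  fvfm <- (fm - f0) / fm
  fm_prime <- fm / (1 + npq_slope * par)
  yield <- fvfm / (1 + y2_decay * par)
  f <- fm_prime * (1 - yield)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f * exp(stats::rnorm(length(f), 0, noise_sd))
    fm_prime <- fm_prime * exp(stats::rnorm(length(fm_prime), 0, noise_sd))
    fm_prime <- pmin(fm_prime, fm)
    f <- pmin(f, fm_prime)
  }
  pam_record(f0, fm, data.frame(par = par, f = f, fm_prime = fm_prime))
}

# sample-standardize x; returns zeros for degenerate input
standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Synthetic station table with controlled chlorophyll-ISIP correlation
#'
#' Emulates the structure of an ocean metatranscriptome station survey:
#' per-station chlorophyll content (log-normal), dissolved iron drawn
#' uniformly inside each configured bin, and ISIP expressions constructed so
#' that the *normalized share* of one target gene (after the percentage and
#' unigene normalization applied by [isip_share()]) has a prescribed Pearson
#' correlation `rho` with chlorophyll inside each bin.
#'
#' The correlated variable is built as an affine combination
#' `v = rho * x + sqrt(1 - rho^2) * e` of the standardized chlorophyll and an
#' independent Gaussian noise term, then mapped affinely to a positive
#' normalized share — affine maps leave Pearson correlation untouched, so the
#' target is hit exactly at the population level, and `rho = 1` yields
#' `r = 1` exactly. With `empirical = TRUE` (default) the noise is
#' orthogonalized against chlorophyll within each bin's sample, so the
#' *sample* correlation equals `rho` exactly in every realization (the same
#' device as `MASS::mvrnorm(empirical = TRUE)`); with `empirical = FALSE` the
#' sample correlation fluctuates around `rho` with the usual
#' `(1 - rho^2)/sqrt(n)` spread. The raw expression of the target gene is
#' back-solved from the share identity so that running the full
#' normalization pipeline recovers the constructed share bit-for-bit.
#'
#' @param seed integer seed (mandatory).
#' @param bins an [iron_bins()] stratification (default
#'   [default_iron_bins()]).
#' @param rho per-bin target Pearson correlation, `|rho| <= 1`; the default
#'   mirrors the qualitative ocean-survey pattern (weak at iron-replete and
#'   iron-starved extremes, strong at intermediate iron).
#' @param n_per_bin stations per bin, `>= 3`.
#' @param gene target gene whose normalized share carries the correlation.
#' @param chl_meanlog,chl_sdlog log-normal parameters of chlorophyll
#'   (mg/m^3).
#' @param share_base,share_cv centre and coefficient of variation of the
#'   normalized share (affine map `share_base * (1 + share_cv * v)`);
#'   `share_cv` must stay well below 1 so shares remain positive.
#' @param unigene_meanlog,unigene_sdlog log-normal parameters of the total
#'   diatom unigene expression.
#' @param other_meanlog,other_sdlog log-normal parameters of the three
#'   non-target ISIP expressions.
#' @param empirical control the sample (`TRUE`, default) or population
#'   (`FALSE`) correlation.
#' @return A [station_table()] with attribute `true_rho` (named by bin
#'   label) and `target_gene`.
#' @examples
#' tab <- make_station_table(seed = 1, rho = c(0.85, 0.65, 0.45, 0))
#' stratified_pearson(tab)
#' @export
make_station_table <- function(seed,
                               bins = default_iron_bins(),
                               rho = c(0.44, 0.84, 0.66, 0),
                               n_per_bin = 15,
                               gene = "isip1",
                               chl_meanlog = log(0.3), chl_sdlog = 0.6,
                               share_base = 2e-4, share_cv = 0.12,
                               unigene_meanlog = log(1e5),
                               unigene_sdlog = 0.2,
                               other_meanlog = log(100), other_sdlog = 0.5,
                               empirical = TRUE) {
  assert_scalar(seed, "seed")
  stopifnot(inherits(bins, "iron_bins"))
  gene <- match.arg(gene, isip_genes)
  if (length(rho) != nrow(bins) || any(!is.finite(rho))) {
    stop("`rho` must supply one finite value per iron bin", call. = FALSE)
  }
  if (any(abs(rho) > 1)) {
    stop("|rho| must not exceed 1", call. = FALSE)
  }
  assert_positive(n_per_bin, "n_per_bin")
  if (n_per_bin < 3) {
    stop("`n_per_bin` must be at least 3", call. = FALSE)
  }
  assert_positive(share_base, "share_base")
  if (share_cv <= 0 || share_cv >= 1) {
    stop("`share_cv` must lie in (0, 1)", call. = FALSE)
  }

  set.seed(seed)
  others <- setdiff(isip_genes, gene)
  per_bin <- lapply(seq_len(nrow(bins)), function(i) {
    n <- n_per_bin
    chl <- stats::rlnorm(n, chl_meanlog, chl_sdlog)
    eps <- stats::rnorm(n)
    if (empirical) {
      x <- standardize(chl)
      e <- eps - mean(eps)
      e <- e - x * sum(e * x) / sum(x * x)
      e <- standardize(e)
    } else {
      mu <- exp(chl_meanlog + chl_sdlog^2 / 2)
      sigma <- sqrt((exp(chl_sdlog^2) - 1)) * mu
      x <- (chl - mu) / sigma
      e <- eps
    }
    v <- rho[i] * x + sqrt(1 - rho[i]^2) * e
    share <- share_base * (1 + share_cv * v)
    share <- pmax(share, share_base * 1e-6)
    unigene <- stats::rlnorm(n, unigene_meanlog, unigene_sdlog)
    if (any(share * unigene >= 100)) {
      stop("constructed share exceeds 100% of unigene total; lower `share_base`",
           call. = FALSE)
    }
    other_expr <- matrix(stats::rlnorm(3L * n, other_meanlog, other_sdlog),
                         nrow = n)
    colnames(other_expr) <- others
    other_sum <- rowSums(other_expr)
    # invert share_norm = (100 g / (g + others)) / unigene for g
    g_expr <- share * other_sum * unigene / (100 - share * unigene)
    df <- data.frame(
      chlorophyll = chl,
      iron = stats::runif(n, bins$lower[i], bins$upper[i])
    )
    df[[gene]] <- g_expr
    for (o in others) df[[o]] <- other_expr[, o]
    df$diatom_unigene_total <- unigene
    df
  })
  out <- do.call(rbind, per_bin)
  out <- cbind(station_id = sprintf("st%03d", seq_len(nrow(out))), out)
  out <- out[c("station_id", "chlorophyll", "iron", isip_genes,
               "diatom_unigene_total")]
  out <- station_table(out)
  attr(out, "true_rho") <- stats::setNames(rho, bins$label)
  attr(out, "target_gene") <- gene
  out
}
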