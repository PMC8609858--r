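#' PAM fluorometry record
#'
#' Holds one pulse-amplitude-modulated fluorometry measurement: the
#' dark-adapted yields `F0` (intrinsic) and `Fm` (maximal, under a saturating
#' pulse) plus a light curve of steps, each with the actinic irradiance `par`
#' (umol/m^2/s), the real-time yield `f` and the light-adapted maximal yield
#' `fm_prime`. Invariants enforced: `Fm >= F0 >= 0` and, per step,
#' `fm_prime >= f >= 0` with `par >= 0`.
#'
#' @param f0 dark-adapted intrinsic fluorescence yield.
#' @param fm dark-adapted maximal fluorescence yield.
#' @param steps data frame with columns `par`, `f`, `fm_prime`.
#' @return An object of class `pam_record`.
#' @export
pam_record <- function(f0, fm, steps) {
  assert_non_negative(f0, "f0")
  assert_non_negative(fm, "fm")
  if (fm < f0) {
    stop("`fm` must be at least `f0`", call. = FALSE)
  }
  if (!is.data.frame(steps) || !all(c("par", "f", "fm_prime") %in% names(steps))) {
    stop("`steps` must be a data frame with columns par, f, fm_prime",
         call. = FALSE)
  }
  with(steps, {
    if (any(par < 0) || any(f < 0) || any(fm_prime < f)) {
      stop("each step must satisfy fm_prime >= f >= 0 and par >= 0",
           call. = FALSE)
    }
  })
  structure(list(f0 = f0, fm = fm,
                 steps = steps[c("par", "f", "fm_prime")]),
            class = "pam_record")
}

#' Maximum quantum yield of photosystem II
#'
#' `Fv/Fm = (Fm - F0) / Fm`, the dark-adapted maximum PSII quantum yield.
#' Healthy diatom cultures sit around 0.6.
#'
#' @param f0,fm dark-adapted intrinsic and maximal fluorescence yields
#'   (vectorized); `fm` must be positive.
#' @return Dimensionless yield in `[0, 1]`.
#' @export
fv_over_fm <- function(f0, fm) {
  stopifnot(is.numeric(f0), is.numeric(fm))
  if (any(fm <= 0)) {
    stop("`fm` must be positive: Fv/Fm is undefined at Fm = 0", call. = FALSE)
  }
  (fm - f0) / fm
}

#' Effective PSII quantum yield under illumination
#'
#' `Y(II) = (Fm' - F) / Fm'`, with `F` the real-time yield and `Fm'` the
#' light-adapted maximal yield at the same step. In the dark-adapted state
#' `Fm' = Fm` and `F = F0`, so Y(II) reduces to Fv/Fm.
#'
#' @param f real-time fluorescence yield (vectorized).
#' @param fm_prime light-adapted maximal yield; must be positive.
#' @return Dimensionless yield.
#' @export
y2 <- function(f, fm_prime) {
  stopifnot(is.numeric(f), is.numeric(fm_prime))
  if (any(fm_prime <= 0)) {
    stop("`fm_prime` must be positive: Y(II) is undefined at Fm' = 0",
         call. = FALSE)
  }
  (fm_prime - f) / fm_prime
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`: the relative loss of maximal fluorescence yield
#' under illumination, non-negative whenever quenching lowers `Fm'` below the
#' dark-adapted `Fm`.
#'
#' @param fm dark-adapted maximal yield (vectorized).
#' @param fm_prime light-adapted maximal yield; must be positive.
#' @return Dimensionless quenching parameter.
#' @export
npq <- function(fm, fm_prime) {
  stopifnot(is.numeric(fm), is.numeric(fm_prime))
  if (any(fm_prime <= 0)) {
    stop("`fm_prime` must be positive: NPQ is undefined at Fm' = 0",
         call. = FALSE)
  }
  (fm - fm_prime) / fm_prime
}

#' Relative electron transport rate through PSII
#'
#' `rETR(II) = Y(II) * PAR * absorption_factor * distribution_factor`. The two
#' instrument factors default to the PAM conventions 0.84 (fraction of
#' incident light absorbed) and 0.5 (fraction directed to PSII); they are
#' instrument- and culture-specific, so rETR values are comparable only within
#' a protocol.
#'
#' @param par actinic irradiance, umol/m^2/s, non-negative (vectorized).
#' @param yield effective PSII quantum yield Y(II) at that irradiance.
#' @param absorption_factor,distribution_factor dimensionless factors in
#'   `(0, 1]`.
#' @return Relative electron transport rate, umol/m^2/s.
#' @export
retr <- function(par, yield, absorption_factor = 0.84,
                 distribution_factor = 0.5) {
  stopifnot(is.numeric(par), is.numeric(yield))
  if (any(par < 0)) {
    stop("`par` must be non-negative", call. = FALSE)
  }
  for (fac in c(absorption_factor, distribution_factor)) {
    if (!is.numeric(fac) || length(fac) != 1L || fac <= 0 || fac > 1) {
      stop("instrument factors must lie in (0, 1]", call. = FALSE)
    }
  }
  yield * par * absorption_factor * distribution_factor
}

#' Photophysiology parameters for a whole light curve
#'
#' Evaluates Y(II), NPQ and rETR(II) at every step of a [pam_record()], plus
#' the dark-adapted Fv/Fm. `y2_denominator = "fm_prime"` (default) uses the
#' light-adapted maximal yield at each step; `"fm_dark"` is a strict-literal
#' mode using the dark-adapted `Fm` throughout — the two coincide in darkness
#' and differ under quenching.
#'
#' @param rec a [pam_record()].
#' @param absorption_factor,distribution_factor passed to [retr()].
#' @param y2_denominator `"fm_prime"` or `"fm_dark"`.
#' @return A data frame with one row per step: `par`, `f`, `fm_prime`, `y2`,
#'   `npq`, `retr`, with the scalar `fv_fm` attached as an attribute.
#' @export
pam_parameters <- function(rec, absorption_factor = 0.84,
                           distribution_factor = 0.5,
                           y2_denominator = c("fm_prime", "fm_dark")) {
  stopifnot(inherits(rec, "pam_record"))
  y2_denominator <- match.arg(y2_denominator)
  st <- rec$steps
  yields <- if (y2_denominator == "fm_prime") {
    y2(st$f, st$fm_prime)
  } else {
    (rec$fm - st$f) / rec$fm
  }
  out <- data.frame(
    par = st$par,
    f = st$f,
    fm_prime = st$fm_prime,
    y2 = yields,
    npq = npq(rec$fm, st$fm_prime),
    retr = retr(st$par, yields, absorption_factor, distribution_factor)
  )
  attr(out, "fv_fm") <- fv_over_fm(rec$f0, rec$fm)
  out
}

#' De-epoxidation state of the diadinoxanthin cycle
#'
#' `DEPS = Dtx / (Ddx + Dtx)`: the fraction of the xanthophyll-cycle pool
#' converted to the photoprotective diatoxanthin form.
#'
#' @param ddx diadinoxanthin concentration, `>= 0` (vectorized).
#' @param dtx diatoxanthin concentration, `>= 0`.
#' @return Dimensionless state in `[0, 1]`.
#' @export
deps <- function(ddx, dtx) {
  stopifnot(is.numeric(ddx), is.numeric(dtx))
  if (any(ddx < 0) || any(dtx < 0)) {
    stop("pigment concentrations must be non-negative", call. = FALSE)
  }
  if (any(ddx + dtx == 0)) {
    stop("DEPS is undefined when Ddx + Dtx = 0", call. = FALSE)
  }
  dtx / (ddx + dtx)
}

#' Read and write PAM light curves as CSV
#'
#' Format: two comment lines `# F0: <value>` and `# Fm: <value>` followed by a
#' CSV table with columns `par`, `f`, `fm_prime`. The reader validates the
#' [pam_record()] invariants.
#'
#' @param path file path.
#' @return `read_pam_csv()` returns a [pam_record()]; `write_pam_csv()`
#'   invisibly returns `path`.
#' @export
read_pam_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  grab <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(hit) != 1L) {
      stop(sprintf("PAM CSV must carry exactly one `# %s:` header line", key),
           call. = FALSE)
    }
    as.numeric(sub(sprintf("^#\\s*%s:\\s*", key), "", hit))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  pam_record(grab("F0"), grab("Fm"), df)
}

#' @rdname read_pam_csv
#' @param rec a [pam_record()] to write.
#' @export
write_pam_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pam_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# F0: %.15g", rec$f0),
               sprintf("# Fm: %.15g", rec$fm)), con)
  utils::write.csv(rec$steps, con, row.names = FALSE)
  invisible(path)
}
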