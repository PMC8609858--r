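#' Unit converters for the interface boundary
#'
#' Internally every quantity is SI: metres, seconds, cells per cubic metre,
#' micromol photons. Laboratory inputs usually arrive as cells/mL and
#' micrometres; these converters are the only sanctioned way to cross that
#' boundary, so unit mixing stays visible at the call site.
#'
#' @param x numeric vector of cell densities in cells per millilitre
#'   (`cells_per_ml`) or lengths in micrometres (`micrometres`).
#' @return Numeric vector in SI units (cells per cubic metre, metres).
#' @examples
#' cells_per_ml(1.6e6)   # 1.6e12 cells per m^3
#' micrometres(3)        # 3e-6 m
#' @export
cells_per_ml <- function(x) {
  stopifnot(is.numeric(x))
  x * 1e6
}

#' @rdname cells_per_ml
#' @export
micrometres <- function(x) {
  stopifnot(is.numeric(x))
  x * 1e-6
}

# internal validation helpers -------------------------------------------------

assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  assert_scalar(x, name)
  if (x <= 0) {
    stop(sprintf("`%s` must be strictly positive (got %g)", name, x),
         call. = FALSE)
  }
  invisible(x)
}

assert_non_negative <- function(x, name) {
  assert_scalar(x, name)
  if (x < 0) {
    stop(sprintf("`%s` must be non-negative (got %g)", name, x),
         call. = FALSE)
  }
  invisible(x)
}
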