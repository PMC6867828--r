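#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: input validation, unit handling,
## first-order (Gaussian) error propagation.

# nm/um/M conversion factors to molar
.unit_to_molar <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Convert a concentration to molar
#'
#' @param x numeric concentration value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return concentration in molar.
#' @export
to_molar <- function(x, unit = "M") {
  if (!unit %in% names(.unit_to_molar)) {
    stop("unknown concentration unit: ", unit, call. = FALSE)
  }
  x * .unit_to_molar[[unit]]
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  .check_finite(x, name)
  if (any(x < 0)) stop("`", name, "` must be non-negative", call. = FALSE)
  invisible(x)
}

.check_pos <- function(x, name) {
  .check_finite(x, name)
  if (any(x <= 0)) stop("`", name, "` must be positive", call. = FALSE)
  invisible(x)
}

# sqrt of sum of squares; NA-tolerant only when all terms are NA
.quad_sum <- function(...) {
  terms <- c(...)
  if (all(is.na(terms))) return(NA_real_)
  sqrt(sum(terms^2, na.rm = TRUE))
}

# standard error of a product x*y with independent Gaussian errors
# (first-order propagation)
.prod_err <- function(x, sx, y, sy) {
  if (is.na(sx) && is.na(sy)) return(NA_real_)
  if (is.na(sx)) sx <- 0
  if (is.na(sy)) sy <- 0
  sqrt((y * sx)^2 + (x * sy)^2)
}

# relative-error propagation for products/quotients: value * sqrt(sum(rel^2))
.rel_err <- function(value, rel_errs) {
  rel_errs <- rel_errs[!is.na(rel_errs)]
  if (length(rel_errs) == 0L) return(NA_real_)
  abs(value) * sqrt(sum(rel_errs^2))
}

# coefficient table of an lm fit; zero-residual fits on exact synthetic data
# trigger a harmless "essentially perfect fit" warning in summary.lm
.lm_coefs <- function(fit) {
  suppressWarnings(summary(fit)$coefficients)
}
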