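#' Fit a collagen standard curve
#'
#' Ordinary least-squares line of dye-binding absorbance (525 nm) on
#' collagen mass for the standard series; samples are later quantified
#' by inverting this line.
#'
#' @param concentrations Standard masses in ug, strictly increasing,
#'   length >= 3.
#' @param absorbances Measured absorbances (same length).
#' @return Object of class `standard_curve`: `slope` (absorbance/ug),
#'   `intercept`, `r_squared`, `valid_range` (ug).
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) < 3) stop("need at least 3 standard points")
  if (length(absorbances) != length(concentrations))
    stop("concentrations and absorbances must have equal length")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  fit <- stats::lm(absorbances ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("assay failure: absorbance does not increase with concentration")
  sst <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 valid_range = range(concentrations)),
            class = "standard_curve")
}

#' Quantify collagen from absorbance
#'
#' Inverts the standard curve:
#' `mass = (absorbance - intercept) / slope * dilution_factor`.
#' Negative masses are clamped to 0 with a warning; readings outside
#' the standard range are flagged via the `"extrapolated"` attribute.
#'
#' @param absorbance Measured absorbance (vectorized).
#' @param curve A [fit_standard_curve()].
#' @param dilution_factor Sample dilution (default 1).
#' @return Collagen mass in ug, with attribute `extrapolated` (logical).
#' @export
quantify_collagen <- function(absorbance, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  raw <- (absorbance - curve$intercept) / curve$slope
  extrap <- raw < curve$valid_range[1] | raw > curve$valid_range[2]
  mass <- raw * dilution_factor
  if (any(mass < 0)) {
    warning("negative collagen mass clamped to 0")
    mass <- pmax(0, mass)
  }
  attr(mass, "extrapolated") <- extrap
  mass
}

#' Collagen synthesis per cell
#'
#' Normalizes total collagen mass by the seeded cell number (the
#' standard 3e5 cells per well unless overridden), in pg per cell.
#'
#' @param mass_ug Collagen mass in ug.
#' @param seeded_cells Cell count (> 0), default 3e5.
#' @return pg per cell.
#' @examples
#' per_cell(60, 3e5)  # 200 pg/cell
#' @export
per_cell <- function(mass_ug, seeded_cells = 3e5) {
  if (any(seeded_cells <= 0)) stop("seeded_cells must be positive")
  mass_ug * 1e6 / seeded_cells
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Collagen standard curve: A = %.4f * ug + %.4f (r^2 = %.4f, range %.1f-%.1f ug)\n",
              x$slope, x$intercept, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
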