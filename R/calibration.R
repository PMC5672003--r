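#' Fit the SEC apparent-mass calibration
#'
#' Ordinary least squares of `log10(mass_kda)` on peak fraction for a set of
#' sizing standards.  On a size-exclusion column larger species elute
#' earlier, so the slope is negative.  Fraction spacing is uniform, so
#' regressing on fraction number is affine-equivalent to regressing on
#' elution volume.
#'
#' @param standards Data frame with columns `mass_kda` and `peak_fraction`
#'   (one row per sizing standard; at least two).
#' @return Object of class `sec_calibration`: `slope` (delta log10 kDa per
#'   fraction), `intercept` (log10 kDa at fraction 0), `r_squared` (defined
#'   for >= 3 standards), `mass_range_kda`, `standards`, and the underlying
#'   `lm` fit.
#' @seealso [apparent_mass()], [predict.sec_calibration()]
#' @examples
#' std <- data.frame(mass_kda = c(100, 10), peak_fraction = c(5, 10))
#' fit_sec_calibration(std)   # slope -0.2, intercept 3
#' @export
fit_sec_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "peak_fraction") %in% names(standards)))
  if (nrow(standards) < 2L)
    stop("calibration needs at least 2 standards")
  if (any(standards$mass_kda <= 0))
    stop("standard masses must be positive")
  if (length(unique(standards$peak_fraction)) < 2L)
    stop("standards elute at identical fractions; cannot fit a line")
  fit <- stats::lm(log10(mass_kda) ~ peak_fraction, data = standards)
  co <- stats::coef(fit)
  # noiseless standards trigger lm's perfect-fit note; r^2 = 1 is intended
  r2 <- if (nrow(standards) >= 3L)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  structure(
    list(slope = unname(co["peak_fraction"]),
         intercept = unname(co["(Intercept)"]),
         r_squared = r2,
         mass_range_kda = range(standards$mass_kda),
         standards = standards,
         fit = fit),
    class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat("SEC calibration: log10(M_app/kDa) =",
      format(x$intercept, digits = 6), "+",
      format(x$slope, digits = 6), "* fraction\n")
  cat("  standards:", nrow(x$standards),
      " mass range:", paste(format(x$mass_range_kda, digits = 4),
                            collapse = " - "), "kDa\n")
  if (!is.na(x$r_squared)) cat("  R-squared:", format(x$r_squared, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.sec_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Convert peak fractions to apparent masses
#'
#' Inverts the calibration line: `M_app = 10^(slope * fraction + intercept)`.
#' Peaks outside the mass range spanned by the standards are converted all
#' the same but flagged as extrapolated.
#'
#' @param model A `sec_calibration` object.
#' @param center Numeric vector of (continuous) peak fractions.
#' @return Data frame with columns `mass_kda` and `extrapolated`.
#' @export
apparent_mass <- function(model, center) {
  stopifnot(inherits(model, "sec_calibration"))
  mass <- 10^(model$slope * center + model$intercept)
  rng <- model$mass_range_kda
  data.frame(
    mass_kda = mass,
    extrapolated = mass < rng[1] * (1 - 1e-9) | mass > rng[2] * (1 + 1e-9))
}

#' @rdname apparent_mass
#' @param object A `sec_calibration` object.
#' @param newdata Numeric vector of peak fractions (defaults to the standard
#'   fractions).
#' @param ... Unused.
#' @export
predict.sec_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$standards$peak_fraction
  apparent_mass(object, newdata)
}

#' @export
plot.sec_calibration <- function(x, ...) {
  graphics::plot(x$standards$peak_fraction, log10(x$standards$mass_kda),
                 xlab = "peak fraction", ylab = "log10 mass (kDa)",
                 main = "SEC calibration", ...)
  graphics::abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Decide whether a peak is resolved by the column
#'
#' A peak is unresolved when it is not at least one fraction past the void:
#' resolved means `center >= void_fraction + 1`.  Schemes without a void
#' (sucrose gradients) resolve every peak.
#'
#' @param center Numeric vector of peak centers (continuous fractions).
#' @param void_fraction Integer void fraction index, or `NULL` for no void.
#' @return Logical vector.
#' @export
is_resolved <- function(center, void_fraction = NULL) {
  if (is.null(void_fraction)) return(rep(TRUE, length(center)))
  center >= void_fraction + 1
}
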