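#' Fit a linear asymmetry-versus-concentration calibration
#'
#' Ordinary least-squares fit of percent asymmetry against agent
#' concentration, asym(c) = b + m c. The fitted line can be inverted
#' to the concentration needed for a target signal change
#' ([detection_threshold()]).
#'
#' @param concs_mM agent concentrations, mM (at least 3 points with at
#'   least 2 distinct values).
#' @param asyms_pct measured asymmetries, percent.
#' @return an object of class \code{cest_calibration} with components
#'   \code{slope} (percent per mM), \code{intercept} (percent),
#'   \code{r_squared} and the underlying \code{lm} fit.
#' @export
#' @examples
#' cal <- fit_calibration(c(0, 1, 2, 4), c(-0.41, 4.3, 9.1, 18.5))
#' coef(cal)
#' detection_threshold(cal, 5)
fit_calibration <- function(concs_mM, asyms_pct) {
  if (length(concs_mM) != length(asyms_pct)) stop("length mismatch")
  if (length(concs_mM) < 3) stop("need at least 3 calibration points")
  if (length(unique(concs_mM)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  fit <- stats::lm(asyms_pct ~ concs_mM)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) stop("degenerate calibration design")
  # collinear designs fit exactly; summary.lm warns about that
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, fit = fit),
            class = "cest_calibration")
}

#' Construct a calibration line from known coefficients
#'
#' @param slope percent asymmetry per mM.
#' @param intercept percent.
#' @param r_squared optional fit quality.
#' @return a \code{cest_calibration}.
#' @export
#' @examples
#' # published Eu-HPDO3A and Yb-HPDO3A calibration lines
#' eu <- calibration_line(4.739, -0.4127)
#' yb <- calibration_line(2.171, -0.9877)
#' detection_threshold(eu, 5)
calibration_line <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    stop("slope and intercept must be finite")
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, fit = NULL),
            class = "cest_calibration")
}

#' @method print cest_calibration
#' @export
print.cest_calibration <- function(x, ...) {
  cat(sprintf("<calibration> asym(%%) = %.4f + %.4f * c(mM)", x$intercept,
              x$slope))
  if (is.finite(x$r_squared)) cat(sprintf("   r^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.cest_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.cest_calibration <- function(object, conc_mM, ...) {
  predict_asymmetry(object, conc_mM)
}

#' Predict asymmetry at a concentration
#'
#' @param line a \code{cest_calibration}.
#' @param conc_mM concentration(s), mM (non-negative).
#' @return predicted asymmetry, percent.
#' @export
predict_asymmetry <- function(line, conc_mM) {
  stopifnot(inherits(line, "cest_calibration"))
  if (any(conc_mM < 0)) stop("conc_mM must be >= 0")
  line$intercept + line$slope * conc_mM
}

#' Concentration required for a target signal change
#'
#' Inverts the calibration line: the concentration at which the
#' predicted asymmetry reaches \code{target_pct}.
#'
#' @param line a \code{cest_calibration} with positive slope.
#' @param target_pct target asymmetry, percent; must exceed the
#'   intercept.
#' @return concentration in mM.
#' @export
detection_threshold <- function(line, target_pct) {
  stopifnot(inherits(line, "cest_calibration"))
  if (line$slope <= 0) stop("detection threshold requires positive slope")
  if (any(target_pct <= line$intercept)) {
    stop("target below the line's intercept is unreachable")
  }
  (target_pct - line$intercept) / line$slope
}
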