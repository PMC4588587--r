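#' Closed-form QUESP saturation-transfer model
#'
#' Steady-state-regime MTR asymmetry of a dilute two-pool system as a
#' function of saturation amplitude:
#' \deqn{MTR = \frac{f_b\,k\,T_{1w}\,\omega_1^2}
#'   {\omega_1^2\,(1 + f_b k T_{1w}) + k^2}}
#' This is the model linearized by the Hanes-Woolf transformation used
#' for exchange-rate estimation.
#'
#' @param k exchange rate solute -> water, s^-1.
#' @param fb solute proton fraction.
#' @param t1w water longitudinal relaxation time, s.
#' @param omega1 saturation amplitude(s), rad/s.
#' @return MTR as a fraction (not percent).
#' @export
#' @examples
#' quesp_mtr_model(5000, 3.6e-5, 3.0, uT_to_rad_s(15))
quesp_mtr_model <- function(k, fb, t1w, omega1) {
  stopifnot(k > 0, fb > 0, t1w > 0, all(omega1 >= 0))
  (fb * k * t1w * omega1^2) / (omega1^2 * (1 + fb * k * t1w) + k^2)
}

#' Hanes-Woolf linear QUESP fit of exchange rate and proton fraction
#'
#' Linearizes the QUESP model by regressing
#' \eqn{y = \omega_1^2 / MTR} on \eqn{x = \omega_1^2} (the Hanes-Woolf
#' transformation, unweighted least squares). With slope \eqn{s} and
#' intercept \eqn{i}, \eqn{A = 1/(s-1)}, \eqn{k = \sqrt{iA}} and
#' \eqn{f_b = A/(k\,T_{1w})}.
#'
#' @param omega1_rad_s saturation amplitudes, rad/s (at least 3
#'   distinct); alternatively supply \code{b1_uT}.
#' @param mtr measured MTR asymmetries at the exchange site, either as
#'   fractions in (0, 1) or as percent (values > 1.5 are interpreted as
#'   percent and divided by 100).
#' @param t1w water T1 used in the model, s.
#' @param b1_uT optional saturation amplitudes in microtesla (converted
#'   with [uT_to_rad_s()]) in place of \code{omega1_rad_s}.
#' @return object of class \code{quesp_fit} with \code{k_exch} (s^-1),
#'   \code{fraction}, \code{r_squared} and the Hanes-Woolf regression.
#' @export
#' @examples
#' w1 <- uT_to_rad_s(c(5, 10, 15, 20, 25))
#' mtr <- quesp_mtr_model(5000, 3.6e-5, 3.0, w1)
#' quesp_fit(w1, mtr, t1w = 3.0)
quesp_fit <- function(omega1_rad_s = NULL, mtr, t1w, b1_uT = NULL) {
  if (is.null(omega1_rad_s)) {
    if (is.null(b1_uT)) stop("supply omega1_rad_s or b1_uT")
    omega1_rad_s <- uT_to_rad_s(b1_uT)
  }
  if (length(omega1_rad_s) != length(mtr)) stop("length mismatch")
  if (length(unique(omega1_rad_s)) < 3) {
    stop("need at least 3 distinct saturation amplitudes")
  }
  if (any(mtr < 0)) stop("MTR values must be non-negative")
  if (max(mtr) > 1.5) mtr <- mtr / 100  # percent at the interface
  if (any(mtr <= 0) || any(mtr >= 1)) {
    stop("MTR values must lie in (0, 1) after conversion")
  }
  if (t1w <= 0) stop("t1w must be positive")

  x <- omega1_rad_s^2
  y <- x / mtr
  hw <- stats::lm(y ~ x)
  cf <- stats::coef(hw)
  i <- unname(cf[1]); s <- unname(cf[2])
  if (s <= 1) {
    stop("Hanes-Woolf slope <= 1: data inconsistent with the QUESP model")
  }
  if (i <= 1e-8 * mean(abs(y))) {
    stop("Hanes-Woolf intercept is not positive: the series carries ",
         "no exchange-rate information (e.g. saturation-independent MTR)")
  }
  A <- 1 / (s - 1)
  k <- sqrt(i * A)
  fb <- A / (k * t1w)
  structure(list(k_exch = k, fraction = fb,
                 r_squared = suppressWarnings(summary(hw)$r.squared),
                 t1w = t1w, hw_fit = hw),
            class = "quesp_fit")
}

#' @method print quesp_fit
#' @export
print.quesp_fit <- function(x, ...) {
  cat(sprintf("<quesp_fit> k = %.0f /s, fb = %.3g, r^2 = %.5f\n",
              x$k_exch, x$fraction, x$r_squared))
  invisible(x)
}

#' @export
coef.quesp_fit <- function(object, ...) {
  c(k_exch = object$k_exch, fraction = object$fraction)
}

#' @method summary quesp_fit
#' @export
summary.quesp_fit <- function(object, ...) {
  cat("Hanes-Woolf linear QUESP fit\n")
  print(object)
  cat(sprintf("  water T1: %g s\n", object$t1w))
  cat("  linear regression (omega1^2/MTR ~ omega1^2):\n")
  print(stats::coef(summary(object$hw_fit)))
  invisible(object)
}
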