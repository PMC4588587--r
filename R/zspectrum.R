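#' Z-spectrum container
#'
#' Normalized (or raw) water saturation signal versus frequency offset
#' for one voxel or ROI. Offsets are sorted increasing on construction.
#'
#' @param offsets_ppm frequency offsets, ppm (positive downfield of
#'   water).
#' @param signal signal intensities, same length.
#' @param s0 reference (unsaturated-equivalent) intensity; required
#'   before asymmetry quantification unless \code{normalized = TRUE}.
#' @param normalized logical; TRUE when \code{signal} is already S/S0.
#' @return object of class \code{zspectrum}.
#' @export
#' @examples
#' z <- zspectrum(c(-20, -18, -16, 16, 18, 20),
#'                c(.97, .95, .96, .90, .80, .89), s0 = 1,
#'                normalized = TRUE)
zspectrum <- function(offsets_ppm, signal, s0 = NULL, normalized = FALSE) {
  if (length(offsets_ppm) != length(signal)) {
    stop("offsets_ppm and signal lengths differ")
  }
  if (anyDuplicated(offsets_ppm)) stop("duplicate offsets")
  o <- order(offsets_ppm)
  if (!is.null(s0)) {
    if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  }
  structure(list(offsets_ppm = offsets_ppm[o], signal = signal[o],
                 s0 = s0, normalized = isTRUE(normalized)),
            class = "zspectrum")
}

#' @method print zspectrum
#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets in [%g, %g] ppm, %s\n",
              length(x$offsets_ppm), min(x$offsets_ppm),
              max(x$offsets_ppm),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
plot.zspectrum <- function(x, ..., xlab = "offset (ppm)",
                           ylab = expression(S / S[0]), type = "b") {
  graphics::plot(x$offsets_ppm, x$signal, xlab = xlab, ylab = ylab,
                 type = type, xlim = rev(range(x$offsets_ppm)), ...)
  invisible(x)
}

#' @export
as.data.frame.zspectrum <- function(x, ...) {
  data.frame(offset_ppm = x$offsets_ppm, signal = x$signal)
}

#' Normalize a z-spectrum by its reference intensity
#'
#' Under the \code{"far_offset"} policy the reference S0 is taken from
#' far off-resonance acquisitions: the -300 ppm image is preferred, and
#' when both +300 and -300 ppm are present their mean is used. The
#' 0 ppm acquisition is never used as a reference (it is fully
#' saturated). Reference offsets are removed from the returned
#' spectrum. Under \code{"zero_power"} the spectrum's stored \code{s0}
#' (an unsaturated acquisition) is used directly.
#'
#' @param raw a [zspectrum()].
#' @param reference_policy \code{"far_offset"} or \code{"zero_power"}.
#' @param far_ppm magnitude of the far-offset reference (default 300).
#' @return a normalized [zspectrum()].
#' @export
normalize_zspectrum <- function(raw,
                                reference_policy = c("far_offset",
                                                     "zero_power"),
                                far_ppm = 300) {
  stopifnot(inherits(raw, "zspectrum"))
  reference_policy <- match.arg(reference_policy)
  if (raw$normalized) return(raw)
  if (reference_policy == "zero_power") {
    if (is.null(raw$s0)) stop("zero_power policy requires s0")
    s0 <- raw$s0
    keep <- rep(TRUE, length(raw$offsets_ppm))
  } else {
    iref <- which(abs(abs(raw$offsets_ppm) - far_ppm) < 1e-9)
    if (!length(iref)) {
      stop("far_offset policy: no +/-", far_ppm, " ppm reference present")
    }
    s0 <- mean(raw$signal[iref])
    keep <- !(seq_along(raw$offsets_ppm) %in% iref)
  }
  if (!is.finite(s0) || s0 <= 0) stop("reference S0 must be positive")
  zspectrum(raw$offsets_ppm[keep], raw$signal[keep] / s0, s0 = 1,
            normalized = TRUE)
}

#' Smoothing-spline fit of a z-spectrum
#'
#' Fits a cubic smoothing spline to the sampled spectrum and returns an
#' evaluable curve over the sampled offset range. With
#' \code{smoothing = 0} the data are interpolated exactly (natural
#' cubic spline). Evaluation outside the sampled range is an error.
#'
#' @param z a [zspectrum()] with at least 4 points.
#' @param smoothing non-negative smoothing parameter (the
#'   \code{lambda} of [stats::smooth.spline()]); \code{NULL} selects it
#'   by generalized cross-validation.
#' @return a function \code{f(offset_ppm)} evaluating the smoothed
#'   curve.
#' @export
spline_smooth <- function(z, smoothing = NULL) {
  stopifnot(inherits(z, "zspectrum"))
  x <- z$offsets_ppm; y <- z$signal
  if (length(x) < 4) stop("need at least 4 points for spline smoothing")
  if (anyDuplicated(x)) stop("duplicate offsets")
  rng <- range(x)
  if (!is.null(smoothing) && smoothing == 0) {
    f0 <- stats::splinefun(x, y, method = "natural")
  } else if (is.null(smoothing)) {
    fit <- stats::smooth.spline(x, y, cv = FALSE)
    f0 <- function(xx) stats::predict(fit, xx)$y
  } else {
    if (smoothing < 0) stop("smoothing must be >= 0")
    fit <- stats::smooth.spline(x, y, lambda = smoothing)
    f0 <- function(xx) stats::predict(fit, xx)$y
  }
  function(offset_ppm) {
    if (any(offset_ppm < rng[1] - 1e-9) || any(offset_ppm > rng[2] + 1e-9)) {
      stop(sprintf("evaluation outside sampled range [%g, %g] ppm",
                   rng[1], rng[2]))
    }
    f0(offset_ppm)
  }
}

#' MTR asymmetry at an offset
#'
#' Magnetization-transfer-ratio asymmetry
#' \eqn{100\,[S(-\Delta) - S(+\Delta)]/S_0} in percent, the basic CEST
#' contrast measure. With the sign convention used throughout (solute
#' sites at positive ppm) a saturable site yields positive asymmetry.
#' When the exact mirror offsets are not sampled, a smoothing curve
#' (from [spline_smooth()]) may be supplied for evaluation.
#'
#' @param z a normalized [zspectrum()].
#' @param offset_ppm positive offset(s) at which to evaluate.
#' @param curve optional evaluable curve from [spline_smooth()].
#' @return asymmetry in percent (vector over \code{offset_ppm}).
#' @export
mtr_asymmetry <- function(z, offset_ppm, curve = NULL) {
  stopifnot(inherits(z, "zspectrum"))
  if (!z$normalized && is.null(z$s0)) {
    stop("spectrum must be normalized (or carry s0)")
  }
  s0 <- if (z$normalized) 1 else z$s0
  lookup <- function(off) {
    i <- which(abs(z$offsets_ppm - off) < 1e-9)
    if (length(i) == 1) return(z$signal[i])
    if (!is.null(curve)) return(curve(off))
    stop(sprintf("offset %g ppm not sampled and no curve supplied", off))
  }
  vapply(offset_ppm, function(d) {
    100 * (lookup(-d) - lookup(d)) / s0
  }, numeric(1))
}

#' Offset band for AUC contrast
#'
#' A set of mirrored offset pairs around an exchange site, used to
#' average asymmetry across neighbouring offsets and suppress
#' single-offset noise.
#'
#' @param center_ppm band center (the exchange-site shift).
#' @param member_offsets_ppm positive member offsets; their negatives
#'   must be acquired too.
#' @return object of class \code{offset_band}.
#' @export
#' @examples
#' eu_band()   # +/-16..20 ppm around the 18 ppm Eu-HPDO3A site
#' yb_band()   # +/-95..99 ppm around the 97 ppm Yb-HPDO3A site
offset_band <- function(center_ppm, member_offsets_ppm) {
  m <- sort(unique(abs(member_offsets_ppm)))
  if (!length(m)) stop("band needs at least one member offset")
  if (center_ppm < min(m) || center_ppm > max(m)) {
    stop("band center must lie within its member offsets")
  }
  structure(list(center_ppm = center_ppm, member_offsets_ppm = m),
            class = "offset_band")
}

#' @rdname offset_band
#' @export
eu_band <- function() offset_band(18, 16:20)

#' @rdname offset_band
#' @export
yb_band <- function() offset_band(97, 95:99)

#' Banded AUC contrast
#'
#' Area-under-the-curve contrast of a z-spectrum over an offset band:
#' the mean of [mtr_asymmetry()] over the band's mirrored pairs. For
#' the unit-spaced bands used here this equals the trapezoidal area
#' divided by the band width, so the result stays in percent and is
#' directly comparable to single-offset asymmetry and to the
#' concentration calibration lines.
#'
#' @param z a normalized [zspectrum()].
#' @param band an [offset_band()].
#' @param curve optional smoothing curve for unsampled offsets.
#' @return band-mean asymmetry, percent.
#' @export
auc_contrast <- function(z, band, curve = NULL) {
  stopifnot(inherits(band, "offset_band"))
  mean(mtr_asymmetry(z, band$member_offsets_ppm, curve = curve))
}
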