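# WASSR B0 field mapping: the low-power direct-saturation dip is
# symmetric about the voxel's true water frequency, so the shift that
# maximizes mirror symmetry of the spline-fitted dip is the per-voxel
# B0 offset.

#' WASSR spectrum
#'
#' A low-power, narrow-offset z-spectrum (water saturation shift
#' referencing). The default protocol samples +/-0.3 ppm in 0.04 ppm
#' steps.
#'
#' @param offsets_ppm fine offset grid (at least 7 points).
#' @param signal normalized signal.
#' @return object of class \code{wassr_spectrum} (also a
#'   \code{zspectrum}).
#' @export
wassr_spectrum <- function(offsets_ppm, signal) {
  if (length(offsets_ppm) < 7) stop("WASSR spectrum needs >= 7 points")
  z <- zspectrum(offsets_ppm, signal, s0 = 1, normalized = TRUE)
  class(z) <- c("wassr_spectrum", class(z))
  z
}

#' WASSR acquisition offset grid
#'
#' @param half_width_ppm half-width of the symmetric grid (default 0.3).
#' @param step_ppm grid step (default 0.04).
#' @return symmetric offset vector.
#' @export
wassr_offsets <- function(half_width_ppm = 0.3, step_ppm = 0.04) {
  g <- seq(step_ppm / 2, half_width_ppm, by = step_ppm)
  g <- sort(c(-g, g))
  if (max(g) < half_width_ppm - 1e-9) {
    g <- sort(c(-half_width_ppm, g, half_width_ppm))
  }
  round(g, 6)
}

#' Maximum-symmetry water center frequency of a WASSR spectrum
#'
#' Finds the shift delta0 minimizing the mirror-asymmetry cost
#' \eqn{\sum_\Delta [C(\delta_0+\Delta) - C(\delta_0-\Delta)]^2} of the
#' spline-fitted dip over the overlap region (offsets where both
#' reflected points lie inside the sampled grid). The search is a
#' 0.001 ppm grid scan followed by local parabolic refinement.
#'
#' @param w a [wassr_spectrum()] (or any contiguous zspectrum).
#' @param search_ppm maximum |delta0| searched (default the grid
#'   half-width).
#' @param smoothing smoothing parameter passed to [spline_smooth()]
#'   (default 0: interpolating spline; WASSR dips are deep relative to
#'   noise at typical SNR).
#' @param grid_ppm scan resolution (default 0.001 ppm).
#' @param window_ppm half-width of the symmetry search window around
#'   the dip minimum (default 0.08 ppm). Restricting the search to the
#'   dip's neighbourhood keeps low-overlap candidates at the grid edge
#'   (whose cost is noise-dominated) from competing with the true
#'   center.
#' @return delta0 in ppm, with attribute \code{boundary} set TRUE when
#'   the minimum sits at the search boundary.
#' @export
max_symmetry_center <- function(w, search_ppm = NULL, smoothing = 0,
                                grid_ppm = 0.001, window_ppm = 0.08) {
  stopifnot(inherits(w, "zspectrum"))
  if (diff(range(w$signal)) < 1e-6) {
    stop("flat spectrum: no symmetry minimum")
  }
  rng <- range(w$offsets_ppm)
  if (is.null(search_ppm)) search_ppm <- min(abs(rng))
  curve <- spline_smooth(w, smoothing = smoothing)

  # coarse stage: the direct-saturation dip minimum
  dense <- seq(rng[1], rng[2], by = grid_ppm)
  c0 <- dense[which.min(curve(dense))]

  cand <- seq(max(-search_ppm, c0 - window_ppm),
              min(search_ppm, c0 + window_ppm), by = grid_ppm)
  if (length(cand) < 3) cand <- seq(-search_ppm, search_ppm,
                                    by = grid_ppm)
  dgrid <- seq(0.002, diff(rng) / 2, by = 0.002)
  cost <- vapply(cand, function(d0) {
    dmax <- min(rng[2] - d0, d0 - rng[1])
    dd <- dgrid[dgrid <= dmax]
    if (length(dd) < 3) return(NA_real_)
    mean((curve(d0 + dd) - curve(d0 - dd))^2)
  }, numeric(1))
  if (all(is.na(cost))) stop("no candidate shift with sufficient overlap")
  i <- which.min(cost)
  d0 <- cand[i]
  boundary <- i == 1 || i == length(cand) ||
    is.na(cost[i - 1]) || is.na(cost[i + 1])
  if (!boundary) {
    cm <- cost[i - 1]; c0 <- cost[i]; cp <- cost[i + 1]
    den <- cm - 2 * c0 + cp
    if (is.finite(den) && den > 0) {
      d0 <- d0 + grid_ppm / 2 * (cm - cp) / den
    }
  }
  structure(d0, boundary = boundary)
}

#' Per-voxel B0 field map from a WASSR offset stack
#'
#' Applies [max_symmetry_center()] to every voxel inside the mask.
#' Voxels outside the mask, or whose fit lands on the search boundary,
#' carry \code{NA} and are excluded from the validity mask.
#'
#' @param wassr_stack an [offset_stack()] acquired with the WASSR
#'   protocol (fine symmetric grid near 0 ppm; an optional far-offset
#'   reference volume is used for normalization).
#' @param mask logical matrix of voxels to fit (default: all voxels).
#' @param ... passed to [max_symmetry_center()].
#' @return object of class \code{field_map}: list with \code{delta0_ppm}
#'   (matrix, NA outside the validity mask) and \code{mask}.
#' @export
field_map <- function(wassr_stack, mask = NULL, ...) {
  stopifnot(inherits(wassr_stack, "offset_stack"))
  dims <- dim(wassr_stack$volumes)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!all(dim(mask) == dims)) stop("mask/stack shape mismatch")

  offs <- wassr_stack$offsets_ppm
  is_ref <- abs(offs) >= 100 | !is.finite(offs)
  fine <- which(!is_ref & abs(offs) <= 1.5)
  refi <- which(is_ref)

  d0 <- matrix(NA_real_, dims[1], dims[2])
  ok <- matrix(FALSE, dims[1], dims[2])
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    sig <- wassr_stack$volumes[i, j, fine]
    if (length(refi)) {
      s0 <- mean(wassr_stack$volumes[i, j, refi])
      if (!is.finite(s0) || s0 <= 0) next
      sig <- sig / s0
    }
    res <- tryCatch(
      max_symmetry_center(wassr_spectrum(offs[fine], sig), ...),
      error = function(e) NULL)
    if (is.null(res)) next
    d0[i, j] <- as.numeric(res)
    ok[i, j] <- !isTRUE(attr(res, "boundary"))
  }
  structure(list(delta0_ppm = d0, mask = ok), class = "field_map")
}

#' @method print field_map
#' @export
print.field_map <- function(x, ...) {
  v <- x$delta0_ppm[x$mask]
  cat(sprintf("<field_map> %d x %d, %d valid voxels, delta0 in [%.3f, %.3f] ppm\n",
              nrow(x$delta0_ppm), ncol(x$delta0_ppm), sum(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Recenter a z-spectrum with a known B0 offset
#'
#' Resamples the spline-fitted spectrum at offsets shifted by the
#' voxel's water-center offset delta0, so that water sits at 0 ppm:
#' corrected S(offset) = measured(offset + delta0). Disjoint sampled
#' segments (e.g. the two sides of an imaging band) are fitted
#' separately, and evaluation up to |delta0| beyond a segment edge uses
#' the natural-spline extension.
#'
#' @param z a normalized [zspectrum()].
#' @param delta0_ppm water-center offset from [max_symmetry_center()].
#' @return a corrected [zspectrum()] on the original offsets.
#' @export
apply_b0_correction <- function(z, delta0_ppm) {
  stopifnot(inherits(z, "zspectrum"))
  if (!is.finite(delta0_ppm)) stop("delta0 must be finite")
  x <- z$offsets_ppm
  if (abs(delta0_ppm) > diff(range(x)) / 2) {
    stop("delta0 exceeds half the sampled range")
  }
  if (delta0_ppm == 0) return(z)

  # split into contiguous segments (imaging bands are widely separated)
  dx <- diff(x)
  gap <- stats::median(dx) * 3
  seg <- cumsum(c(1, as.numeric(dx > gap)))
  ynew <- numeric(length(x))
  for (s in unique(seg)) {
    i <- which(seg == s)
    xi <- x[i]
    if (length(i) >= 4) {
      f <- stats::splinefun(xi, z$signal[i], method = "natural")
    } else if (length(i) >= 2) {
      f <- stats::approxfun(xi, z$signal[i], rule = 2)
    } else {
      f <- function(v) z$signal[i]
    }
    ynew[i] <- f(xi + delta0_ppm)
  }
  zspectrum(x, ynew, s0 = z$s0, normalized = z$normalized)
}
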