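# Voxelwise dual-channel CEST mapping: banded AUC asymmetry maps from
# offset stacks, with the B0 correction applied to the Eu (18 ppm)
# channel only, per the acquisition policy that the 97 ppm Yb channel
# is insensitive to B0 inhomogeneity at this scale.

#' Per-voxel AUC contrast map
#'
#' For every masked voxel: assemble the z-spectrum across the stack's
#' offsets, normalize by the far-offset reference (-300 ppm image,
#' averaged with +300 ppm when both are present), optionally recenter
#' with the voxel's B0 offset, and compute the banded AUC asymmetry.
#'
#' @param stack an [offset_stack()] containing the band offsets and a
#'   far-offset reference.
#' @param band an [offset_band()].
#' @param fieldmap optional [field_map()]; voxels with a valid fit are
#'   recentred with [apply_b0_correction()] before the band average.
#' @param mask logical matrix of voxels to map (default all).
#' @param far_ppm magnitude of the far-offset reference (default 300).
#' @return object of class \code{contrast_map}: \code{values_pct}
#'   matrix (NA outside mask), \code{channel}, \code{mask}.
#' @export
compute_channel_map <- function(stack, band, fieldmap = NULL,
                                mask = NULL, far_ppm = 300) {
  stopifnot(inherits(stack, "offset_stack"),
            inherits(band, "offset_band"))
  dims <- dim(stack$volumes)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!all(dim(mask) == dims)) stop("mask/stack shape mismatch")
  if (!is.null(fieldmap)) {
    stopifnot(inherits(fieldmap, "field_map"))
    if (!all(dim(fieldmap$delta0_ppm) == dims)) {
      stop("fieldmap geometry does not match the stack")
    }
  }
  offs <- stack$offsets_ppm
  iref <- which(abs(abs(offs) - far_ppm) < 1e-9)
  if (!length(iref)) stop("no far-offset reference volume in stack")
  s0 <- apply(stack$volumes[, , iref, drop = FALSE], c(1, 2), mean)
  if (any(s0[mask] <= 0)) stop("non-positive reference signal in mask")

  members <- band$member_offsets_ppm
  ipos <- match(members, offs)
  ineg <- match(-members, offs)
  if (anyNA(ipos) || anyNA(ineg)) {
    miss <- c(members[is.na(ipos)], -members[is.na(ineg)])
    stop("band offsets missing from stack: ",
         paste(miss, collapse = ", "))
  }

  # vectorized band-mean asymmetry (no B0 shift)
  asym <- matrix(0, dims[1], dims[2])
  for (p in seq_along(members)) {
    asym <- asym + (stack$volumes[, , ineg[p]] -
                    stack$volumes[, , ipos[p]])
  }
  values <- 100 * asym / (length(members) * s0)

  if (!is.null(fieldmap)) {
    iband <- sort(c(ipos, ineg))
    redo <- which(mask & fieldmap$mask &
                    is.finite(fieldmap$delta0_ppm) &
                    fieldmap$delta0_ppm != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(redo))) {
      i <- redo[r, 1]; j <- redo[r, 2]
      z <- zspectrum(offs[iband],
                     stack$volumes[i, j, iband] / s0[i, j],
                     s0 = 1, normalized = TRUE)
      zc <- apply_b0_correction(z, fieldmap$delta0_ppm[i, j])
      values[i, j] <- auc_contrast(zc, band)
    }
  }
  values[!mask] <- NA_real_
  structure(list(values_pct = values, channel = band_label(band),
                 mask = mask, band = band),
            class = "contrast_map")
}

band_label <- function(band) {
  if (isTRUE(all.equal(band$center_ppm, 18))) return("Eu18")
  if (isTRUE(all.equal(band$center_ppm, 97))) return("Yb97")
  sprintf("band%g", band$center_ppm)
}

#' @method print contrast_map
#' @export
print.contrast_map <- function(x, ...) {
  v <- x$values_pct[x$mask]
  cat(sprintf("<contrast_map %s> %d x %d, mean %.2f%%, range [%.2f, %.2f]%%\n",
              x$channel, nrow(x$values_pct), ncol(x$values_pct),
              mean(v), min(v), max(v)))
  invisible(x)
}

#' Dual-channel Eu/Yb contrast maps
#'
#' Computes the Eu (18 ppm band) map with per-voxel B0 correction and
#' the Yb (97 ppm band) map without correction — the default analysis
#' policy for this agent pair.
#'
#' @param eu_stack,yb_stack [offset_stack()]s for the two channels.
#' @param fieldmap optional [field_map()] (applied to the Eu channel).
#' @param mask optional logical matrix.
#' @return named list of two \code{contrast_map}s (\code{eu},
#'   \code{yb}).
#' @export
dual_channel_maps <- function(eu_stack, yb_stack, fieldmap = NULL,
                              mask = NULL) {
  list(eu = compute_channel_map(eu_stack, eu_band(), fieldmap = fieldmap,
                                mask = mask),
       yb = compute_channel_map(yb_stack, yb_band(), fieldmap = NULL,
                                mask = mask))
}

#' Compare labeled and control ROIs on a contrast map
#'
#' Difference of ROI means with its standard error and a Welch
#' two-sample t-test p-value, treating voxels as independent samples.
#' Degenerate (zero-variance) ROIs are handled: equal constants give
#' p = 1, different constants give p = 0.
#'
#' @param map a \code{contrast_map}.
#' @param labeled_mask,control_mask disjoint, non-empty logical
#'   matrices.
#' @return object of class \code{roi_stats}: \code{mean_diff_pct},
#'   \code{sem_pct}, \code{p_value}, \code{n_voxels} (named vector).
#' @export
roi_compare <- function(map, labeled_mask, control_mask) {
  stopifnot(inherits(map, "contrast_map"))
  if (any(labeled_mask & control_mask)) stop("ROIs must be disjoint")
  a <- map$values_pct[labeled_mask]
  b <- map$values_pct[control_mask]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("empty ROI")
  diff <- mean(a) - mean(b)
  sem <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (!is.finite(sem)) sem <- 0
  if (sem < .Machine$double.eps^0.5 * max(1, abs(diff))) {
    p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
  } else {
    p <- stats::t.test(a, b)$p.value
  }
  structure(list(mean_diff_pct = diff, sem_pct = sem, p_value = p,
                 n_voxels = c(labeled = length(a), control = length(b))),
            class = "roi_stats")
}

#' @method print roi_stats
#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> diff = %.2f%% +/- %.2f (p = %.3g), n = %d vs %d\n",
              x$mean_diff_pct, x$sem_pct, x$p_value,
              x$n_voxels["labeled"], x$n_voxels["control"]))
  invisible(x)
}

#' Thresholded channel overlay on a T2-weighted image
#'
#' Renders voxels whose channel contrast exceeds a per-channel
#' threshold in the channel colour (Eu blue, Yb red by default) over
#' the grayscale anatomical image, and counts supra-threshold voxels
#' per channel. Colour intensity scales linearly from the threshold to
#' the channel maximum.
#'
#' @param maps named list of \code{contrast_map}s (e.g. from
#'   [dual_channel_maps()]).
#' @param t2w_image numeric matrix, same geometry.
#' @param thresholds_pct named or positional numeric thresholds
#'   (percent, >= 0), one per map.
#' @param palette channel colours (any R colour), one per map.
#' @param file optional PNG path; written with [png::writePNG()].
#' @return object of class \code{overlay_scene}: \code{rgb} array
#'   (nx x ny x 3), \code{counts} of supra-threshold voxels per
#'   channel, \code{thresholds_pct}.
#' @export
threshold_overlay <- function(maps, t2w_image, thresholds_pct,
                              palette = c("blue", "red"), file = NULL) {
  if (inherits(maps, "contrast_map")) maps <- list(maps)
  if (length(thresholds_pct) == 1) {
    thresholds_pct <- rep(thresholds_pct, length(maps))
  }
  stopifnot(length(thresholds_pct) == length(maps),
            length(palette) >= length(maps))
  if (any(thresholds_pct < 0)) stop("thresholds must be >= 0")
  dims <- dim(t2w_image)
  bg <- t2w_image - min(t2w_image)
  if (max(bg) > 0) bg <- bg / max(bg)
  rgb <- array(rep(bg, 3), dim = c(dims, 3))

  counts <- integer(length(maps))
  names(counts) <- vapply(maps, `[[`, character(1), "channel")
  for (m in seq_along(maps)) {
    map <- maps[[m]]
    if (!all(dim(map$values_pct) == dims)) stop("geometry mismatch")
    v <- map$values_pct
    hot <- is.finite(v) & v > thresholds_pct[m]
    counts[m] <- sum(hot)
    if (!any(hot)) next
    vmax <- max(v[hot])
    scale <- if (vmax > thresholds_pct[m]) {
      (v - thresholds_pct[m]) / (vmax - thresholds_pct[m])
    } else matrix(1, dims[1], dims[2])
    scale <- pmin(pmax(scale, 0.25), 1)  # keep faint voxels visible
    col <- grDevices::col2rgb(palette[m]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[hot] <- pmin(1, plane[hot] * (1 - scale[hot]) +
                           col[ch] * scale[hot])
      rgb[, , ch] <- plane
    }
  }
  scene <- structure(list(rgb = rgb, counts = counts,
                          thresholds_pct = thresholds_pct),
                     class = "overlay_scene")
  if (!is.null(file)) {
    # PNG rows run top-to-bottom; transpose to image convention
    png::writePNG(aperm(rgb, c(2, 1, 3)), file)
    scene$file <- file
  }
  scene
}

#' @method print overlay_scene
#' @export
print.overlay_scene <- function(x, ...) {
  cat("<overlay_scene> supra-threshold voxels:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Lesion mask from a T2-weighted image
#'
#' Thresholds the image at 1 standard deviation above the mean of a
#' reference (contralateral / undamaged) region — the standard
#' hyperintensity rule for delineating a stroke cavity.
#'
#' @param t2w_image numeric matrix.
#' @param reference_mask logical matrix of the undamaged reference
#'   region.
#' @param n_sd number of standard deviations above the reference mean
#'   (default 1).
#' @return logical lesion mask.
#' @export
lesion_mask_from_t2w <- function(t2w_image, reference_mask, n_sd = 1) {
  stopifnot(all(dim(t2w_image) == dim(reference_mask)))
  ref <- t2w_image[reference_mask]
  if (!length(ref)) stop("empty reference region")
  t2w_image > mean(ref) + n_sd * stats::sd(ref)
}
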