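#' 4D saturation-offset image stack
#'
#' An image volume per saturation offset for one slice:
#' \code{volumes[x, y, offset]} with a sidecar offset table. Reference
#' offsets (0 and -300 ppm in the imaging protocols) are ordinary
#' members of the offset list and are consumed during normalization.
#'
#' @param volumes numeric array, \code{nx x ny x n_offsets}.
#' @param offsets_ppm offset per volume (no duplicates).
#' @param averages number of repeat acquisitions merged into this stack.
#' @param geometry optional named list of voxel-grid metadata (e.g.
#'   \code{pixdim}).
#' @return object of class \code{offset_stack}.
#' @export
offset_stack <- function(volumes, offsets_ppm, averages = 1,
                         geometry = list()) {
  if (length(dim(volumes)) == 2) {
    dim(volumes) <- c(dim(volumes), 1)
  }
  if (length(dim(volumes)) != 3) {
    stop("volumes must be an nx x ny x n_offsets array")
  }
  if (dim(volumes)[3] != length(offsets_ppm)) {
    stop(sprintf("volume count (%d) does not match offset count (%d)",
                 dim(volumes)[3], length(offsets_ppm)))
  }
  if (anyDuplicated(offsets_ppm)) stop("duplicate offsets in stack")
  if (!all(is.finite(volumes))) stop("non-finite voxels in stack")
  structure(list(volumes = volumes, offsets_ppm = offsets_ppm,
                 averages = averages, geometry = geometry),
            class = "offset_stack")
}

#' @method print offset_stack
#' @export
print.offset_stack <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<offset_stack> %d x %d voxels, %d offsets, %d average(s)\n",
              d[1], d[2], d[3], x$averages))
  invisible(x)
}

#' Average repeat acquisitions voxelwise
#'
#' Voxelwise mean of stacks acquired with identical offsets and
#' geometry; the \code{averages} counters are summed. Averaging n
#' i.i.d.-noise acquisitions reduces voxel noise by sqrt(n) at the
#' same effect size.
#'
#' @param stacks list of [offset_stack()] objects.
#' @return the averaged [offset_stack()].
#' @export
average_stacks <- function(stacks) {
  if (inherits(stacks, "offset_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1)
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    stopifnot(inherits(s, "offset_stack"))
    if (!isTRUE(all.equal(s$offsets_ppm, ref$offsets_ppm)) ||
        !all(dim(s$volumes) == dim(ref$volumes))) {
      stop("stacks have mismatched offsets or geometry")
    }
  }
  vols <- Reduce(`+`, lapply(stacks, `[[`, "volumes")) / length(stacks)
  offset_stack(vols, ref$offsets_ppm,
               averages = sum(vapply(stacks, `[[`, numeric(1), "averages")),
               geometry = ref$geometry)
}

#' Extract one voxel's z-spectrum from a stack
#'
#' @param stack an [offset_stack()].
#' @param i,j voxel indices.
#' @return a raw [zspectrum()] over the stack's offsets.
#' @export
voxel_spectrum <- function(stack, i, j) {
  stopifnot(inherits(stack, "offset_stack"))
  zspectrum(stack$offsets_ppm, stack$volumes[i, j, ],
            normalized = FALSE)
}

#' Read / write an offset stack as NIfTI plus a sidecar offset table
#'
#' The image is stored as a NIfTI volume whose last dimension indexes
#' saturation offsets; the offsets live in a two-column CSV
#' (\code{volume, offset_ppm}) next to it.
#'
#' @param path NIfTI file path (\code{.nii} or \code{.nii.gz}).
#' @param offsets_path CSV path; defaults to \code{path} with the
#'   extension replaced by \code{_offsets.csv}.
#' @param stack an [offset_stack()] (for writing).
#' @return [read_offset_stack()] returns an [offset_stack()];
#'   [write_offset_stack()] returns \code{path} invisibly.
#' @export
read_offset_stack <- function(path, offsets_path = NULL) {
  if (is.null(offsets_path)) offsets_path <- default_offsets_path(path)
  img <- RNifti::readNifti(path)
  tab <- utils::read.csv(offsets_path)
  if (!"offset_ppm" %in% names(tab)) {
    stop("offsets CSV must have an offset_ppm column")
  }
  offs <- tab$offset_ppm
  if (anyDuplicated(offs)) stop("offsets CSV contains a duplicate offset")
  arr <- as.array(img)
  d <- dim(arr)
  # stored as nx x ny x 1 x n or nx x ny x n
  if (length(d) == 4 && d[3] == 1) {
    arr <- array(arr, dim = d[c(1, 2, 4)])
    d <- dim(arr)
  }
  if (d[length(d)] != length(offs)) {
    stop(sprintf("NIfTI has %d volumes but the offset table lists %d",
                 d[length(d)], length(offs)))
  }
  offset_stack(arr, offs,
               geometry = list(pixdim = RNifti::pixdim(img)))
}

#' @rdname read_offset_stack
#' @export
write_offset_stack <- function(stack, path, offsets_path = NULL) {
  stopifnot(inherits(stack, "offset_stack"))
  if (is.null(offsets_path)) offsets_path <- default_offsets_path(path)
  RNifti::writeNifti(RNifti::asNifti(stack$volumes), path)
  utils::write.csv(
    data.frame(volume = seq_along(stack$offsets_ppm),
               offset_ppm = stack$offsets_ppm),
    offsets_path, row.names = FALSE)
  invisible(path)
}

default_offsets_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, "_offsets.csv")
}
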