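#' 3D intensity volume with voxel spacing and optional brain mask
#'
#' `volume_image()` is the container every stage of the pipeline operates on:
#' a 3-axis real-valued intensity grid, per-axis voxel size in millimetres and,
#' once brain extraction has run (or for synthetic phantoms, from construction),
#' a logical brain mask of the same shape.
#'
#' Grids are indexed `(x, y, z)`, 0-based in documentation and 1-based in R
#' code, spatial axis fastest.  Orientation metadata read from NIfTI headers is
#' carried through untouched; the network is orientation-agnostic after
#' resampling.
#'
#' @param grid 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param mask optional logical array, same shape as `grid`, `TRUE` = brain.
#' @return An object of class `volume_image`: a list with elements `grid`,
#'   `spacing` and `mask`.
#' @examples
#' v <- volume_image(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(v$grid)
#' @export
volume_image <- function(grid, spacing = c(1, 1, 1), mask = NULL) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("`grid` must be a 3-axis array; got dimensions [",
         paste(dim(grid), collapse = " x "), "]")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel sizes (mm)")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(grid))) {
      stop("mask shape [", paste(dim(mask), collapse = " x "),
           "] does not match grid shape [", paste(dim(grid), collapse = " x "), "]")
    }
    storage.mode(mask) <- "logical"
  }
  structure(list(grid = grid, spacing = spacing, mask = mask),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm",
      if (!is.null(x$mask)) sprintf(", mask (%d brain voxels)", sum(x$mask)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into a [volume_image]. A singleton fourth
#' axis (e.g. a one-volume 4D series) is squeezed away; any other non-3D
#' payload is rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [volume_image]; intensities are unmodified.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI image (", path,
                                           "): ", conditionMessage(e)))
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  grid <- as.array(img)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (all(extra == 1L)) {
      grid <- array(grid, dim = d[1:3])
      d <- d[1:3]
    }
  }
  if (length(dim(grid)) != 3L) {
    stop("NIfTI payload is not 3D after squeezing singleton axes: shape [",
         paste(d, collapse = " x "), "]")
  }
  spacing <- if (length(pd) >= 3L) abs(pd[1:3]) else c(1, 1, 1)
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  volume_image(grid, spacing = spacing)
}

#' Write a NIfTI volume
#'
#' @param vol a [volume_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  # RNifti signals an unwritable path as a warning; treat it as an I/O error
  withCallingHandlers(
    tryCatch(RNifti::writeNifti(img, path),
             error = function(e) stop("cannot write NIfTI to ", path, ": ",
                                      conditionMessage(e))),
    warning = function(w) stop("cannot write NIfTI to ", path, ": ",
                               conditionMessage(w)))
  if (!file.exists(path)) stop("cannot write NIfTI to ", path)
  invisible(path)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; `NA` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
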