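#' Grad-CAM volumetric saliency for the age estimate
#'
#' Gradient-weighted class-activation mapping on the scalar age output:
#' channel weights are the spatial mean of the gradient of the predicted age
#' with respect to a chosen block's pre-pool activation; the map is the
#' rectified weighted channel sum, trilinearly upsampled to the input shape
#' and min-max normalised to `[0, 1]`.  By construction the map is
#' non-negative before normalisation and invariant to uniform rescaling of
#' the output layer's weights.
#'
#' @param model a trained `brainage_model`.
#' @param volume preprocessed input ([volume_image] or 3D array) matching the
#'   configured input shape.
#' @param sex 0 or 1.
#' @param source_block block index whose pre-pool activation is used;
#'   defaults to the final residual block.
#' @return An object of class `saliency_map`: `grid` (same shape as the
#'   input, values in `[0, 1]`) and `source_block`.  An all-zero gradient
#'   yields a zero map with a warning.
#' @export
gradcam <- function(model, volume, sex, source_block = NULL) {
  stopifnot(inherits(model, "brainage_model"), sex %in% c(0, 1))
  cfg <- model$config
  if (is.null(source_block)) {
    source_block <- max(which(cfg$types == "res"))
  }
  if (!source_block %in% seq_along(cfg$types)) {
    stop("source_block must be a block index in 1..", length(cfg$types))
  }
  grid <- if (inherits(volume, "volume_image")) volume$grid else volume
  if (!identical(as.integer(dim(grid)), cfg$input_shape)) {
    stop("input shape [", paste(dim(grid), collapse = " x "),
         "] does not match the configured [",
         paste(cfg$input_shape, collapse = " x "), "]")
  }
  xb <- array(grid, c(dim(grid), 1L, 1L))
  fw <- net_forward(model, xb, sex, training = FALSE, keep_cache = TRUE)
  bw <- net_backward(model, fw$cache, dpred = 1, keep_prepool = TRUE)
  A <- fw$cache$blocks[[source_block]]$A       # pre-pool activation
  dA <- bw$d_prepool[[source_block]]
  nc <- dim(A)[4]
  w <- vapply(seq_len(nc), function(c) mean(dA[, , , c, 1]), numeric(1))
  cam <- array(0, dim(A)[1:3])
  for (c in seq_len(nc)) cam <- cam + w[c] * A[, , , c, 1]
  cam <- pmax(cam, 0)
  if (max(cam) == 0) {
    warning("all-zero saliency map (zero gradients at the source block)")
    out <- array(0, dim(grid))
  } else {
    out <- .resample3(cam, dim(grid), "trilinear")
    out <- pmax(out, 0)
    out <- (out - min(out)) / (max(out) - min(out))
  }
  structure(list(grid = out, source_block = source_block),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> ", paste(dim(x$grid), collapse = " x "),
      ", block ", x$source_block,
      ", mean saliency ", signif(mean(x$grid), 3), "\n", sep = "")
  invisible(x)
}

#' Write a saliency map as NIfTI alongside its input
#'
#' @param map a [gradcam] saliency map.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing voxel spacing carried into the header.
#' @return Invisibly, `path`.
#' @export
write_saliency <- function(map, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(map, "saliency_map"))
  write_volume(volume_image(map$grid, spacing = spacing), path)
}
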