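#' Pre-processing chain for structural MRI volumes
#'
#' The chain mirrors standard structural-MRI preparation: brain extraction
#' (mask application with an automatic threshold-based fallback), removal of
#' the smooth multiplicative intensity-inhomogeneity field, resampling to the
#' network's input grid, and within-mask intensity normalisation.
#'
#' @name preprocess
NULL

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# 3x3x3 box dilation as three sequential 1D max-filters (separable).
.dilate_box <- function(m) {
  d <- dim(m)
  sh <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    src <- if (by > 0) c(1L, seq_len(n - 1)) else c(seq_len(n - 1) + 1L, n)
    idx[[axis]] <- src
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (axis in 1:3) {
    m <- m | sh(m, axis, 1L) | sh(m, axis, -1L)
  }
  m
}

.erode_box <- function(m) !.dilate_box(!m)

.closing_box <- function(m, iter = 1L) {
  for (i in seq_len(iter)) m <- .dilate_box(m)
  for (i in seq_len(iter)) m <- .erode_box(m)
  m
}

.largest_component <- function(m) {
  lab <- cpp_label_components(m, dim(m))
  if (max(lab) == 0L) return(m & FALSE)
  tab <- tabulate(lab[lab > 0L])
  array(lab == which.max(tab), dim(m))
}

# Automatic brain mask: Otsu foreground -> largest component -> closing ->
# identify the bright shell (second Otsu inside the foreground) -> take the
# shell's enclosed interior (components of the shell complement that do not
# touch the volume border).
fallback_brain_mask <- function(grid) {
  t1 <- otsu_threshold(as.vector(grid))
  fg <- grid > t1
  if (!any(fg)) stop("brain extraction failed: no foreground above threshold")
  fg <- .largest_component(fg)
  t2 <- otsu_threshold(grid[fg])
  shell <- .closing_box(fg & grid > t2)   # closing seals 1-voxel shell gaps
  comp <- cpp_label_components(!shell, dim(shell))
  d <- dim(grid)
  border_labels <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ],
                            comp[, d[2], ], comp[, , 1], comp[, , d[3]]))
  interior <- array(comp > 0L & !(comp %in% border_labels), d)
  mask <- interior & !shell
  if (!any(mask)) stop("brain extraction failed: shell interior is empty")
  mask
}

#' Brain extraction
#'
#' Zeroes every voxel outside the brain mask.  Precedence for the mask:
#' an explicitly supplied `mask`, then an external extraction `tool` (a
#' function `volume_image -> logical array`, e.g. a wrapper around a U-Net
#' skull stripper), then the built-in threshold fallback
#' (Otsu foreground, largest connected component, binary closing, interior of
#' the bright skull/scalp shell).
#'
#' @param vol a [volume_image].
#' @param mask optional logical array matching `vol`'s shape.
#' @param tool optional function computing a mask from `vol`.
#' @return The extracted [volume_image] with its `mask` field set.
#' @export
extract_brain <- function(vol, mask = NULL, tool = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(vol$grid))) {
      stop("mask shape [", paste(dim(mask), collapse = " x "),
           "] does not match volume shape [",
           paste(dim(vol$grid), collapse = " x "), "]")
    }
    storage.mode(mask) <- "logical"
  } else if (!is.null(tool)) {
    mask <- tool(vol)
    if (!identical(dim(mask), dim(vol$grid))) {
      stop("extraction tool returned a mask of the wrong shape")
    }
    storage.mode(mask) <- "logical"
  } else {
    mask <- fallback_brain_mask(vol$grid)
  }
  if (!any(mask)) stop("brain extraction failed: empty mask")
  grid <- vol$grid
  grid[!mask] <- 0
  volume_image(grid, spacing = vol$spacing, mask = mask)
}

# all monomials x^i y^j z^k with 1 <= i+j+k <= order, on normalised coords
.poly_design <- function(coords, order) {
  pw <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  pw <- pw[rowSums(pw) >= 1 & rowSums(pw) <= order, , drop = FALSE]
  X <- matrix(1, nrow(coords), nrow(pw))
  for (m in seq_len(nrow(pw))) {
    X[, m] <- coords[, 1]^pw$i[m] * coords[, 2]^pw$j[m] * coords[, 3]^pw$k[m]
  }
  X
}

.norm_coords <- function(shape, idx = NULL) {
  g <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                             z = seq_len(shape[3])))
  g <- sweep(g, 2, (shape + 1) / 2)
  g <- sweep(g, 2, pmax(shape - 1, 1) / 2, "/")
  if (is.null(idx)) g else g[idx, , drop = FALSE]
}

#' Smooth multiplicative bias-field correction
#'
#' Estimates the smooth multiplicative intensity-inhomogeneity field by a
#' robust polynomial fit (Huber M-estimate) of the given order to the
#' log-intensities inside the mask, and divides it out; robustness keeps
#' genuine structure (e.g. the dark ventricles) from leaking into the field
#' estimate, the same role the histogram-sharpening step plays in N4-style
#' correctors.  Mean intensity inside the mask is preserved.  `n4_hook`
#' substitutes an external correction implementation
#' (`function(volume_image, mask) -> volume_image`) when one is available.
#'
#' @param vol a [volume_image] (strictly positive inside the mask; otherwise a
#'   documented positive shift is applied before taking logs).
#' @param mask logical array; defaults to `vol$mask`.
#' @param order polynomial order of the log-field (default 2); order 0 is a
#'   global rescaling.
#' @param n4_hook optional external corrector.
#' @return The corrected [volume_image].
#' @export
correct_bias <- function(vol, mask = vol$mask, order = 2L, n4_hook = NULL) {
  stopifnot(inherits(vol, "volume_image"), order >= 0)
  if (is.null(mask) || !any(mask)) stop("bias correction needs a non-empty mask")
  if (!identical(dim(mask), dim(vol$grid))) stop("mask shape mismatch")
  if (!is.null(n4_hook)) return(n4_hook(vol, mask))
  grid <- vol$grid
  inside <- grid[mask]
  shift <- 0
  if (min(inside) <= 0) {
    shift <- 1e-6 * max(abs(inside)) - min(inside) + 1e-12
    inside <- inside + shift
  }
  logi <- log(inside)
  if (order == 0L) {
    field_log <- array(0, dim(grid))  # constant field: global rescale only
  } else {
    idx <- which(mask)
    X <- cbind(1, .poly_design(.norm_coords(dim(grid), idx), order))
    fit <- tryCatch(MASS::rlm(X, logi, maxit = 50), error = function(e) NULL)
    beta <- if (!is.null(fit)) stats::coef(fit) else {
      stats::lm.fit(X, logi)$coefficients
    }
    beta[!is.finite(beta)] <- 0
    Xall <- cbind(1, .poly_design(.norm_coords(dim(grid)), order))
    field_log <- array(as.vector(Xall %*% beta), dim(grid))
    field_log <- field_log - mean(field_log[mask])
  }
  corrected <- (grid + shift) / exp(field_log)
  scale <- mean(vol$grid[mask]) / mean(corrected[mask])
  corrected <- corrected * scale
  corrected[vol$grid == 0 & !mask] <- 0
  volume_image(corrected, spacing = vol$spacing, mask = vol$mask)
}

# 1D normalised Gaussian smoothing along each axis (edge-renormalised),
# used as an anti-aliasing prefilter before heavy downsampling.
.gauss_smooth <- function(grid, sigma) {
  d <- dim(grid)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-0.5 * ((-half):half / s)^2)
    perm <- c(axis, setdiff(1:3, axis))
    g <- aperm(grid, perm)
    m <- matrix(g, nrow = d[axis])
    num <- stats::filter(m, kern, sides = 2)
    den <- stats::filter(matrix(1, nrow(m), ncol(m)), kern, sides = 2)
    sm <- num / den
    # filter() leaves NA within half-window of the edges; renormalise there
    na_rows <- which(rowSums(is.na(sm)) > 0)
    for (i in na_rows) {
      lo <- max(1L, i - half); hi <- min(nrow(m), i + half)
      kk <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      sm[i, ] <- crossprod(kk, m[lo:hi, , drop = FALSE]) / sum(kk)
    }
    g <- array(as.numeric(sm), dim = d[perm])
    grid <- aperm(g, order(perm))
  }
  grid
}

# trilinear (or nearest-neighbour) resampling with half-pixel centre alignment
.resample3 <- function(grid, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(grid)
  f <- d / target
  src <- lapply(1:3, function(a) pmin(pmax((seq_len(target[a]) - 0.5) * f[a] - 0.5, 0), d[a] - 1))
  if (method == "nearest") {
    ix <- lapply(1:3, function(a) pmin(d[a], pmax(1L, as.integer(round(src[[a]])) + 1L)))
    return(grid[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - 1))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
  w <- lapply(1:3, function(a) src[[a]] - lo[[a]])
  out <- array(0, target)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- (if (cx) hi[[1]] else lo[[1]]) + 1L
    iy <- (if (cy) hi[[2]] else lo[[2]]) + 1L
    iz <- (if (cz) hi[[3]] else lo[[3]]) + 1L
    wx <- if (cx) w[[1]] else 1 - w[[1]]
    wy <- if (cy) w[[2]] else 1 - w[[2]]
    wz <- if (cz) w[[3]] else 1 - w[[3]]
    wt <- outer(outer(wx, wy), wz)
    out <- out + wt * grid[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample a volume onto a target grid
#'
#' Trilinear interpolation for intensities (half-pixel centre-aligned),
#' nearest-neighbour for the mask; voxel spacing is rescaled so physical
#' extent is preserved.  When an axis is downsampled by more than a factor of
#' 2 and `antialias = TRUE`, a Gaussian prefilter (sigma `(f - 1)/2` voxels
#' for scale factor `f`) suppresses aliasing first.  Axes are stretched
#' independently; anisotropic inputs are therefore distorted onto the target
#' grid, which the downstream network tolerates because every training input
#' passes through the same mapping.
#'
#' @param vol a [volume_image].
#' @param target_shape integer length-3, all entries >= 2.
#' @param antialias apply the Gaussian prefilter for heavy downsampling.
#' @return The resampled [volume_image].
#' @export
resize_volume <- function(vol, target_shape, antialias = TRUE) {
  stopifnot(inherits(vol, "volume_image"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L)) {
    stop("target_shape must be 3 integers >= 2")
  }
  d <- dim(vol$grid)
  f <- d / target_shape
  grid <- vol$grid
  if (antialias && any(f > 2)) {
    sigma <- ifelse(f > 2, (f - 1) / 2, 0)
    grid <- .gauss_smooth(grid, sigma)
  }
  out_grid <- .resample3(grid, target_shape, "trilinear")
  out_mask <- if (!is.null(vol$mask)) {
    array(.resample3(array(as.numeric(vol$mask), d), target_shape, "nearest") > 0.5,
          target_shape)
  } else NULL
  volume_image(out_grid, spacing = vol$spacing * f, mask = out_mask)
}

#' Within-mask z-score intensity normalisation
#'
#' Centres and scales intensities to mean 0, sd 1 inside the mask (the whole
#' grid when no mask is present); voxels outside the mask are set to 0.  A
#' zero-variance region yields zeros with a warning.  Idempotent up to
#' floating-point rounding.
#'
#' @param vol a [volume_image].
#' @return The normalised [volume_image].
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  mask <- if (!is.null(vol$mask)) vol$mask else array(TRUE, dim(vol$grid))
  vals <- vol$grid[mask]
  s <- stats::sd(vals)
  grid <- array(0, dim(vol$grid))
  if (!is.finite(s) || s == 0) {
    warning("zero variance inside mask; normalised volume is all zeros")
  } else {
    grid[mask] <- (vals - mean(vals)) / s
  }
  volume_image(grid, spacing = vol$spacing, mask = vol$mask)
}

#' Configuration of the preprocessing pipeline
#'
#' @param extract,bias,resize,normalize stage toggles.
#' @param mask optional explicit brain mask for extraction.
#' @param extraction_tool optional external extraction function.
#' @param bias_order polynomial order of the bias-field estimate.
#' @param target_shape network input grid (default `c(64, 64, 32)`).
#' @param antialias Gaussian prefilter toggle for heavy downsampling.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(extract = TRUE, bias = TRUE, resize = TRUE,
                              normalize = TRUE, mask = NULL,
                              extraction_tool = NULL, bias_order = 2L,
                              target_shape = c(64, 64, 32), antialias = TRUE) {
  structure(list(extract = extract, bias = bias, resize = resize,
                 normalize = normalize, mask = mask,
                 extraction_tool = extraction_tool, bias_order = bias_order,
                 target_shape = as.integer(target_shape), antialias = antialias),
            class = "preprocess_config")
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: brain extraction, bias-field correction, resampling to
#' the network grid, within-mask z-scoring.  Each stage can be switched off in
#' the config; stage failures are re-raised with the stage name attached.
#' The pipeline is deterministic: there is no randomness in any stage.
#'
#' @param vol a [volume_image].
#' @param cfg a [preprocess_config].
#' @return The preprocessed [volume_image].
#' @export
preprocess_pipeline <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "volume_image"), inherits(cfg, "preprocess_config"))
  run <- function(stage, f) {
    tryCatch(f(), error = function(e) {
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  if (cfg$extract) {
    vol <- run("extract_brain", function()
      extract_brain(vol, mask = cfg$mask, tool = cfg$extraction_tool))
  }
  if (cfg$bias) {
    vol <- run("correct_bias", function()
      correct_bias(vol, order = cfg$bias_order))
  }
  if (cfg$resize && !identical(dim(vol$grid), as.integer(cfg$target_shape))) {
    vol <- run("resize_volume", function()
      resize_volume(vol, cfg$target_shape, antialias = cfg$antialias))
  }
  if (cfg$normalize) {
    vol <- run("normalize_intensity", function() normalize_intensity(vol))
  }
  vol
}
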