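#' Extract fused penultimate features for the SVR head
#'
#' Runs the trained network in inference mode over every scan and returns the
#' penultimate dense-layer activation (default) concatenated with the sex
#' code: one row per scan, `dense_units + 1` columns.  `layer = "flatten"`
#' substitutes the flattened terminal convolutional map for the dense
#' activation instead.  Deterministic.
#'
#' @param model a trained `brainage_model`.
#' @param data a [brainage_dataset].
#' @param batch_size evaluation batch size.
#' @param layer `"dense"` (the post-ELU penultimate activation) or
#'   `"flatten"` (the flattened terminal convolutional features).
#' @return Numeric matrix `n x (p + 1)` with the matched `age` vector
#'   attached as attribute `"age"`.
#' @export
extract_features <- function(model, data, batch_size = 16L,
                             layer = c("dense", "flatten")) {
  stopifnot(inherits(model, "brainage_model"), inherits(data, "brainage_dataset"))
  layer <- match.arg(layer)
  p <- if (layer == "dense") model$config$dense_units else .flat_dim(model$config)
  out <- matrix(0, data$n, p + 1L)
  for (idx in .batch_indices(data$n, batch_size)) {
    b <- .dataset_slice(data, idx)
    r <- net_forward(model, b$x, b$sex, training = FALSE)
    f <- if (layer == "dense") r$features else r$flat
    out[idx, ] <- cbind(f, b$sex)
  }
  colnames(out) <- c(sprintf("f%03d", seq_len(p)), "sex")
  attr(out, "age") <- data$age
  out
}

#' SVR head hyperparameters
#'
#' Conventional epsilon-insensitive kernel-regression defaults: radial-basis
#' kernel, `C = 1`, `epsilon = 0.1`; `gamma` defaults to one over the number
#' of (retained) feature columns.
#'
#' @param kernel `e1071::svm` kernel name.
#' @param cost regularisation constant C.
#' @param epsilon width of the insensitive tube (years).
#' @param gamma RBF width; `NULL` = `1/ncol`.
#' @param standardize `"pooled"` (default: centre each column, divide all by
#'   the pooled standard deviation, preserving the learned relative feature
#'   magnitudes) or `"column"` (classic per-column z-scoring; rescales
#'   near-constant noise-dominated activations to unit variance, which
#'   distorts the kernel metric for homogeneous deep features).
#' @return A list of class `svr_params`.
#' @export
svr_params <- function(kernel = "radial", cost = 1.0, epsilon = 0.1,
                       gamma = NULL, standardize = c("pooled", "column")) {
  standardize <- match.arg(standardize)
  structure(list(kernel = kernel, cost = cost, epsilon = epsilon,
                 gamma = gamma, standardize = standardize),
            class = "svr_params")
}

#' Fit the support-vector-regression head
#'
#' Centres every feature column by its training mean and scales by the
#' pooled (or, optionally, per-column) training standard deviation —
#' zero-variance columns are dropped from the kernel input, and the
#' statistics are stored with the head so test rows can never influence
#' them — then fits epsilon-insensitive SVR of age on the fused features.
#' The age target is standardised by its training moments as well — with the
#' conventional `C = 1` the epsilon-tube regression is only well scaled for
#' an O(1) response — and predictions are mapped back to years; `epsilon` is
#' interpreted in years and converted to the standardised scale internally.
#'
#' @param features `n x p` feature matrix from [extract_features].
#' @param age training ages; defaults to the matrix's `"age"` attribute.
#' @param params an [svr_params].
#' @return An object of class `svr_head`.
#' @export
fit_svr <- function(features, age = attr(features, "age"),
                    params = svr_params()) {
  stopifnot(is.matrix(features))
  if (nrow(features) < 2) stop("need at least 2 training rows to fit the SVR head")
  if (is.null(age) || length(age) != nrow(features)) {
    stop("ages must match the feature rows")
  }
  center <- colMeans(features)
  col_sd <- apply(features, 2, stats::sd)
  keep <- which(col_sd > 0)
  if (!length(keep)) stop("all feature columns are constant")
  scale <- if (params$standardize == "pooled") {
    rep(sqrt(mean(col_sd[keep]^2)), length(col_sd))
  } else col_sd
  xs <- sweep(sweep(features[, keep, drop = FALSE], 2, center[keep]),
              2, scale[keep], "/")
  gamma <- if (is.null(params$gamma)) 1 / ncol(xs) else params$gamma
  age_center <- mean(age)
  age_scale <- stats::sd(age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  fit <- e1071::svm(x = xs, y = (age - age_center) / age_scale,
                    type = "eps-regression",
                    kernel = params$kernel, cost = params$cost,
                    epsilon = params$epsilon / age_scale, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale, keep = keep,
                 age_center = age_center, age_scale = age_scale,
                 n_features = ncol(features), params = params),
            class = "svr_head")
}

#' Predict ages with the SVR head
#'
#' @param head an [svr_head] from [fit_svr].
#' @param features feature matrix with the same column count as at fit time.
#' @return Numeric vector of predicted ages, one per row.
#' @export
predict_svr <- function(head, features) {
  stopifnot(inherits(head, "svr_head"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != head$n_features) {
    stop("feature column mismatch: head expects ", head$n_features,
         ", got ", ncol(features))
  }
  xs <- sweep(sweep(features[, head$keep, drop = FALSE], 2,
                    head$center[head$keep]), 2, head$scale[head$keep], "/")
  as.numeric(stats::predict(head$fit, xs)) * head$age_scale + head$age_center
}
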