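#' Architecture of the attention-augmented 3D residual regression network
#'
#' The network alternates residual convolution blocks with self-attention
#' blocks.  Each block halves every spatial dimension via 2x2x2 max-pooling,
#' so the input grid must be divisible by `2^length(features)`.  The default
#' configuration — three residual blocks of 8, 32 and 128 features with
#' attention blocks of 16 and 64 features in the second and fourth positions,
#' 3x3x3 convolutions, 1x1x1 shortcut projections, ELU (alpha = 1), a
#' 128-unit L2-regularised dense layer with dropout 0.2 and a sex-fused final
#' linear unit — operates on a 64 x 64 x 32 input grid.
#'
#' A residual block computes `H(x) = shortcut(x) + BN(conv(ELU(BN(conv(x)))))`
#' (the shortcut is a 1x1x1 projection so the pointwise sum is well defined),
#' then `maxpool(ELU(H))`.  An attention block computes query and value
#' embeddings with two independent 3x3x3 convolutions, applies dot-product
#' attention over all flattened spatial positions (keys are the values; no
#' separate key embedding), concatenates query and attention output along
#' channels, projects back to the block's feature count with a third 3x3x3
#' convolution, and applies BN, ELU and max-pooling.
#'
#' @param features per-block output feature counts, strictly increasing.
#' @param types block types, `"res"` or `"att"`, same length as `features`.
#' @param input_shape spatial input grid, divisible by `2^length(features)`.
#' @param dense_units width of the penultimate dense layer (default 128).
#' @param dense_l2 L2 regularisation weight on the dense layer (default 1e-4).
#' @param dropout_rate dropout rate after the dense ELU (default 0.2).
#' @param use_scale divide attention scores by `sqrt(C)` (default off,
#'   matching the stock unscaled dot-product layer).
#' @param elu_alpha ELU saturation parameter (default 1).
#' @param attention_chunk row-chunk size bounding attention score memory
#'   (0 = materialise all `N x N` scores at once; the default 256 bounds
#'   score memory and is considerably cache-friendlier).
#' @param bn_momentum decay of the batch-norm running statistics (default
#'   0.9, so the inference statistics track the batch moments within a few
#'   dozen updates — appropriate for the short desk-scale schedules; raise
#'   towards 0.99 for long runs).
#' @return An object of class `network_config`.
#' @export
network_config <- function(features = c(8, 16, 32, 64, 128),
                           types = c("res", "att", "res", "att", "res"),
                           input_shape = c(64, 64, 32),
                           dense_units = 128L,
                           dense_l2 = 1e-4,
                           dropout_rate = 0.2,
                           use_scale = FALSE,
                           elu_alpha = 1.0,
                           attention_chunk = 256L,
                           bn_momentum = 0.9) {
  features <- as.integer(features)
  if (length(features) != length(types)) stop("features and types lengths differ")
  if (!all(types %in% c("res", "att"))) stop("types must be 'res' or 'att'")
  if (any(diff(features) <= 0)) {
    stop("block feature counts must be strictly increasing: ",
         paste(features, collapse = ", "))
  }
  input_shape <- as.integer(input_shape)
  nb <- length(features)
  if (any(input_shape %% (2L^nb) != 0L)) {
    stop("input shape [", paste(input_shape, collapse = " x "),
         "] must be divisible by 2^", nb, " (one halving per block)")
  }
  structure(list(features = features, types = types,
                 input_shape = input_shape,
                 dense_units = as.integer(dense_units),
                 dense_l2 = dense_l2, dropout_rate = dropout_rate,
                 use_scale = use_scale, elu_alpha = elu_alpha,
                 attention_chunk = as.integer(attention_chunk),
                 bn_momentum = bn_momentum,
                 conv_kernel = 3L, shortcut_kernel = 1L, pool = 2L),
            class = "network_config")
}

# flattened feature length entering the dense layer
.flat_dim <- function(config) {
  nb <- length(config$features)
  prod(config$input_shape %/% (2L^nb)) * config$features[nb]
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

.conv_init <- function(k, cin, cout) {
  list(w = .he_init(c(k, k, k, cin, cout), k^3 * cin),
       b = numeric(cout))
}

.bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
.bn_state_init <- function(c) list(mean = rep(0, c), var = rep(1, c))

#' Build an (untrained) network
#'
#' Allocates and seeds all trainable parameters of the configured
#' architecture.  Two builds with the same seed are identical.
#'
#' @param config a [network_config].
#' @param seed integer seed for parameter initialisation.
#' @return An object of class `brainage_model` holding `config`, `params`,
#'   batch-norm running statistics in `state`, and `training_seed`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    blocks <- vector("list", length(config$features))
    state <- vector("list", length(config$features))
    cin <- 1L
    for (i in seq_along(config$features)) {
      f <- config$features[i]
      if (config$types[i] == "res") {
        blocks[[i]] <- list(
          conv1 = .conv_init(3L, cin, f),
          conv2 = .conv_init(3L, f, f),
          shortcut = .conv_init(1L, cin, f),
          bn1 = .bn_init(f), bn2 = .bn_init(f))
        state[[i]] <- list(bn1 = .bn_state_init(f), bn2 = .bn_state_init(f))
      } else {
        blocks[[i]] <- list(
          q = .conv_init(3L, cin, f),
          v = .conv_init(3L, cin, f),
          proj = .conv_init(3L, 2L * f, f),
          bn = .bn_init(f))
        state[[i]] <- list(bn = .bn_state_init(f))
      }
      cin <- f
    }
    D <- .flat_dim(config)
    du <- config$dense_units
    params <- list(
      blocks = blocks,
      dense_w = array(stats::rnorm(D * du, sd = sqrt(2 / (D + du))), c(D, du)),
      dense_b = numeric(du),
      out_w = array(stats::rnorm(du + 1L, sd = sqrt(2 / (du + 2))), c(du + 1L, 1L)),
      out_b = 0)
    structure(list(config = config, params = params, state = state,
                   training_seed = as.integer(seed), history = NULL,
                   trained = FALSE),
              class = "brainage_model")
  })
}

#' @export
print.brainage_model <- function(x, ...) {
  cfg <- x$config
  cat("<brainage_model> ", paste(cfg$input_shape, collapse = "x"), " input; blocks ",
      paste(sprintf("%s(%d)", toupper(substr(cfg$types, 1, 1)), cfg$features),
            collapse = " -> "),
      "; dense ", cfg$dense_units,
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  best val loss ", signif(min(x$history$val_loss, na.rm = TRUE), 4),
        " over ", nrow(x$history), " epochs\n", sep = "")
  }
  invisible(x)
}

# ---- internal batched forward / backward engine --------------------------

.res_block_fwd <- function(x, p, st, training, alpha, mom = 0.9) {
  c1 <- conv_fwd(x, p$conv1, 3L)
  b1 <- bn_fwd(c1, p$bn1, st$bn1, training, mom)
  y1 <- elu_fwd(b1$y, alpha)
  c2 <- conv_fwd(y1, p$conv2, 3L)
  b2 <- bn_fwd(c2, p$bn2, st$bn2, training, mom)
  s <- conv_fwd(x, p$shortcut, 1L)
  H <- s + b2$y
  A <- elu_fwd(H, alpha)
  pl <- pool_fwd(A)
  list(y = pl$y,
       state = list(bn1 = b1$state, bn2 = b2$state),
       cache = list(x = x, b1 = b1, y1 = y1, b2 = b2, H = H, A = A, pl = pl))
}

.res_block_bwd <- function(p, cache, dy, alpha) {
  dA <- pool_bwd(cache$pl, dy)
  dH <- dA * elu_grad_from_y(cache$H, cache$A, alpha)
  bb2 <- bn_bwd(cache$b2$cache, p$bn2, dH)
  cv2 <- conv_bwd(cache$y1, p$conv2, bb2$dx, 3L)
  db1y <- cv2$dx * elu_grad_from_y(cache$b1$y, cache$y1, alpha)
  bb1 <- bn_bwd(cache$b1$cache, p$bn1, db1y)
  cv1 <- conv_bwd(cache$x, p$conv1, bb1$dx, 3L)
  cvs <- conv_bwd(cache$x, p$shortcut, dH, 1L)
  list(dx = cv1$dx + cvs$dx,
       d_prepool = dA,
       grads = list(conv1 = list(w = cv1$dw, b = cv1$db),
                    conv2 = list(w = cv2$dw, b = cv2$db),
                    shortcut = list(w = cvs$dw, b = cvs$db),
                    bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                    bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta)))
}

.att_block_fwd <- function(x, p, st, training, use_scale, chunk, alpha, mom = 0.9) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) {
    stop("spatial dimensions [", paste(d[1:3], collapse = " x "),
         "] must be even before 2 x 2 x 2 max-pooling")
  }
  Q <- conv_fwd(x, p$q, 3L)
  V <- conv_fwd(x, p$v, 3L)
  dq <- dim(Q)
  N <- prod(dq[1:3])
  adim <- c(N, dq[4], dq[5])
  att <- cpp_attention_fwd(Q, V, adim, use_scale, chunk)
  dim(att) <- dq
  Con <- channel_concat(Q, att)
  P <- conv_fwd(Con, p$proj, 3L)
  b <- bn_fwd(P, p$bn, st$bn, training, mom)
  A <- elu_fwd(b$y, alpha)
  pl <- pool_fwd(A)
  list(y = pl$y,
       state = list(bn = b$state),
       cache = list(x = x, Q = Q, V = V, adim = adim, att = att, Con = Con,
                    b = b, A = A, pl = pl))
}

.att_block_bwd <- function(p, cache, dy, use_scale, chunk, alpha) {
  dA <- pool_bwd(cache$pl, dy)
  dB <- dA * elu_grad_from_y(cache$b$y, cache$A, alpha)
  bb <- bn_bwd(cache$b$cache, p$bn, dB)
  cvp <- conv_bwd(cache$Con, p$proj, bb$dx, 3L)
  f <- dim(cache$Q)[4]
  dQ1 <- cvp$dx[, , , seq_len(f), , drop = FALSE]
  datt <- cvp$dx[, , , f + seq_len(f), , drop = FALSE]
  ab <- cpp_attention_bwd(cache$Q, cache$V, datt, cache$adim, use_scale, chunk)
  dQ <- dQ1 + array(ab$dq, dim(cache$Q))
  dV <- array(ab$dv, dim(cache$V))
  cvq <- conv_bwd(cache$x, p$q, dQ, 3L)
  cvv <- conv_bwd(cache$x, p$v, dV, 3L)
  list(dx = cvq$dx + cvv$dx,
       d_prepool = dA,
       grads = list(q = list(w = cvq$dw, b = cvq$db),
                    v = list(w = cvv$dw, b = cvv$db),
                    proj = list(w = cvp$dw, b = cvp$db),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

# Batched forward pass.  xb: (X,Y,Z,1,B); sex: length-B in {0,1}.
# Returns predictions, penultimate features (post-ELU dense activations with
# dropout off), per-layer caches when keep_cache, and updated BN state.
net_forward <- function(model, xb, sex, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  d <- dim(xb)
  if (!identical(as.integer(d[1:3]), cfg$input_shape)) {
    stop("input shape [", paste(d[1:3], collapse = " x "),
         "] does not match the configured [",
         paste(cfg$input_shape, collapse = " x "), "]")
  }
  B <- d[5]
  stopifnot(length(sex) == B)
  x <- xb
  caches <- vector("list", length(cfg$features))
  for (i in seq_along(cfg$features)) {
    if (cfg$types[i] == "res") {
      r <- .res_block_fwd(x, p$blocks[[i]], st[[i]], training, cfg$elu_alpha,
                          cfg$bn_momentum)
    } else {
      r <- .att_block_fwd(x, p$blocks[[i]], st[[i]], training,
                          cfg$use_scale, cfg$attention_chunk, cfg$elu_alpha,
                          cfg$bn_momentum)
    }
    x <- r$y
    st[[i]] <- r$state
    if (keep_cache) caches[[i]] <- r$cache
  }
  flat <- t(matrix(x, ncol = B))                       # B x D
  h <- sweep(flat %*% p$dense_w, 2, p$dense_b, "+")    # B x du
  hE <- elu_fwd(h, cfg$elu_alpha)
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    dropmask <- matrix((stats::runif(length(hE)) < keep) / keep,
                       nrow(hE), ncol(hE))
    hD <- hE * dropmask
  } else {
    dropmask <- NULL
    hD <- hE
  }
  fused <- cbind(hD, as.numeric(sex))                  # B x (du + 1)
  pred <- as.vector(fused %*% p$out_w + p$out_b)
  list(pred = pred, features = hE, flat = flat, state = st,
       cache = if (keep_cache) {
         list(blocks = caches, block_out = x, flat = flat, h = h, hE = hE,
              dropmask = dropmask, fused = fused)
       } else NULL)
}

# Backward pass from d(loss)/d(pred).  Returns parameter gradients shaped
# like model$params and, when keep_prepool, the gradient at each block's
# pre-pool activation (used by Grad-CAM).
net_backward <- function(model, cache, dpred, keep_prepool = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- length(dpred)
  dy <- matrix(dpred, ncol = 1)
  dout_w <- crossprod(cache$fused, dy)
  dout_b <- sum(dy)
  dfused <- dy %*% t(p$out_w)
  du <- cfg$dense_units
  dhD <- dfused[, seq_len(du), drop = FALSE]
  dhE <- if (!is.null(cache$dropmask)) dhD * cache$dropmask else dhD
  dh <- dhE * elu_grad_from_y(cache$h, cache$hE, cfg$elu_alpha)
  ddense_w <- crossprod(cache$flat, dh)
  ddense_b <- colSums(dh)
  dflat <- dh %*% t(p$dense_w)
  dx <- array(as.vector(t(dflat)), dim(cache$block_out))
  blocks <- vector("list", length(cfg$features))
  prepool <- if (keep_prepool) vector("list", length(cfg$features)) else NULL
  for (i in rev(seq_along(cfg$features))) {
    if (cfg$types[i] == "res") {
      r <- .res_block_bwd(p$blocks[[i]], cache$blocks[[i]], dx, cfg$elu_alpha)
    } else {
      r <- .att_block_bwd(p$blocks[[i]], cache$blocks[[i]], dx,
                          cfg$use_scale, cfg$attention_chunk, cfg$elu_alpha)
    }
    blocks[[i]] <- r$grads
    if (keep_prepool) prepool[[i]] <- r$d_prepool
    dx <- r$dx
  }
  list(grads = list(blocks = blocks, dense_w = ddense_w, dense_b = ddense_b,
                    out_w = dout_w, out_b = dout_b),
       d_input = dx, d_prepool = prepool)
}

# ---- exported single-sample operations -----------------------------------

.as_batch1 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("feature map must have 3 spatial axes + channels")
  array(x, c(d, 1L))
}

#' Residual block forward pass
#'
#' `H(x) = shortcut(x) + BN(conv(ELU(BN(conv(x)))))`, then
#' `maxpool(ELU(H))`: the input bypasses the convolution path through a
#' 1x1x1 projection and is combined by pointwise sum.  Spatial dimensions
#' halve; channels become the block's feature count.
#'
#' @param x feature map, array `(X, Y, Z, C)` (or `(X, Y, Z)` for 1 channel);
#'   spatial dims must be even.
#' @param params list with `conv1`, `conv2`, `shortcut` (each `w`, `b`),
#'   `bn1`, `bn2` (each `gamma`, `beta`), e.g. one entry of
#'   `build_network(...)$params$blocks`.
#' @param state optional batch-norm running statistics (`bn1`, `bn2`, each
#'   `mean`, `var`); defaults to mean 0 / variance 1 (identity-like BN).
#' @param alpha ELU saturation parameter.
#' @return The output feature map `(X/2, Y/2, Z/2, features)`.
#' @export
res_block_forward <- function(x, params, state = NULL, alpha = 1) {
  xb <- .as_batch1(x)
  if (any(dim(xb)[1:3] %% 2L != 0L)) {
    stop("spatial dimensions [", paste(dim(xb)[1:3], collapse = " x "),
         "] must be even before 2 x 2 x 2 max-pooling")
  }
  f <- length(params$bn1$gamma)
  if (is.null(state)) state <- list(bn1 = .bn_state_init(f), bn2 = .bn_state_init(f))
  r <- .res_block_fwd(xb, params, state, training = FALSE, alpha = alpha)
  array(r$y, dim(r$y)[1:4])
}

#' Dot-product attention over flattened spatial positions
#'
#' Flattens all spatial positions into a sequence of length `N = X*Y*Z` with
#' `C` channels, computes scores `S[i, j] = Q[i] . V[j]` (divided by
#' `sqrt(C)` when `use_scale`), row-softmax weights, and returns
#' `out[i] = sum_j w[i, j] V[j]` reshaped to the query's shape.  Keys are the
#' values: there is no separate key embedding.  Every output position is a
#' convex combination of value rows.
#'
#' @param Q,V query and value feature maps: equally shaped `(X, Y, Z, C)`
#'   arrays or `N x C` matrices.
#' @param use_scale scale scores by `1/sqrt(C)`.
#' @param chunk bound on score rows held in memory at once (0 = all).
#' @return Attention output with the same shape as `Q`.
#' @export
attention_forward <- function(Q, V, use_scale = FALSE, chunk = 0L) {
  if (!identical(dim(Q), dim(V))) {
    stop("Q shape [", paste(dim(Q), collapse = " x "),
         "] and V shape [", paste(dim(V), collapse = " x "), "] differ")
  }
  d <- dim(Q)
  if (is.matrix(Q)) {
    adim <- c(nrow(Q), ncol(Q), 1L)
  } else if (length(d) == 4L) {
    adim <- c(prod(d[1:3]), d[4], 1L)
  } else {
    stop("Q and V must be N x C matrices or (X, Y, Z, C) arrays")
  }
  out <- cpp_attention_fwd(as.numeric(Q), as.numeric(V), as.integer(adim),
                           use_scale, as.integer(chunk))
  dim(out) <- d
  out
}

#' Attention block forward pass
#'
#' Query and value embeddings by two independent 3x3x3 convolutions,
#' dot-product attention over spatial positions, channel concatenation of the
#' query with the attention output, a third 3x3x3 convolution projecting back
#' to the block's feature count, then BN, ELU and 2x2x2 max-pooling.
#'
#' @param x input feature map `(X, Y, Z, C)`; spatial dims must be even.
#' @param params list with `q`, `v`, `proj` (each `w`, `b`) and `bn`.
#' @param state optional BN running statistics (`bn`).
#' @param use_scale,chunk see [attention_forward].
#' @param alpha ELU saturation parameter.
#' @return The output feature map `(X/2, Y/2, Z/2, features)`.
#' @export
attention_block_forward <- function(x, params, state = NULL, use_scale = FALSE,
                                    chunk = 0L, alpha = 1) {
  xb <- .as_batch1(x)
  f <- length(params$bn$gamma)
  if (is.null(state)) state <- list(bn = .bn_state_init(f))
  r <- .att_block_fwd(xb, params, state, training = FALSE,
                      use_scale = use_scale, chunk = chunk, alpha = alpha)
  array(r$y, dim(r$y)[1:4])
}

#' Run the network on one preprocessed volume
#'
#' Inference-mode forward pass: dropout disabled, batch norm using running
#' statistics — a pure function of `(parameters, input)`.  Returns both the
#' scalar age estimate and the penultimate dense-layer activation (post-ELU),
#' the feature vector the SVR head consumes.
#'
#' @param model a `brainage_model`.
#' @param volume a [volume_image] or 3D array matching the configured input
#'   shape (preprocessed).
#' @param sex 0 or 1.
#' @return A list with `age` (years) and `features` (length `dense_units`).
#' @export
model_forward <- function(model, volume, sex) {
  stopifnot(inherits(model, "brainage_model"), sex %in% c(0, 1))
  grid <- if (inherits(volume, "volume_image")) volume$grid else volume
  if (!identical(as.integer(dim(grid)), model$config$input_shape)) {
    stop("input shape [", paste(dim(grid), collapse = " x "),
         "] does not match the configured [",
         paste(model$config$input_shape, collapse = " x "), "]")
  }
  xb <- array(grid, c(dim(grid), 1L, 1L))
  r <- net_forward(model, xb, sex, training = FALSE)
  list(age = r$pred[1], features = as.vector(r$features))
}

#' Save / load a trained model
#'
#' The checkpoint embeds the architecture configuration, all parameters,
#' batch-norm running statistics and the training history.
#'
#' @param model a `brainage_model`.
#' @param path checkpoint file path.
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "brainage_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "brainage_model")) stop("not a brainage model checkpoint: ", path)
  m
}
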