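# Internal layer primitives operating on batched feature maps stored as
# (X, Y, Z, C, B) arrays (spatial fastest, then channel, then sample).
# Forward functions return caches carrying exactly what their backward needs.

conv_fwd <- function(x, p, k) {
  cpp_conv3d_fwd(x, dim(x), p$w, p$b, k)
}

conv_bwd <- function(x, p, dy, k) {
  r <- cpp_conv3d_bwd(x, dim(x), p$w, dy, k, length(p$b))
  list(dx = r$dx,
       dw = array(r$dw, dim(p$w)),
       db = as.numeric(r$db))
}

elu_fwd <- function(x, alpha = 1) {
  neg <- x < 0
  y <- x
  y[neg] <- alpha * (exp(x[neg]) - 1)
  y
}

# derivative expressed through the forward output (1 for x > 0, y + alpha else)
elu_grad_from_y <- function(x, y, alpha = 1) {
  g <- array(1, dim(x))
  neg <- x < 0
  g[neg] <- y[neg] + alpha
  g
}

# Batch normalisation over (spatial x batch) per channel.  Keras-style
# epsilon and running-statistics momentum; training mode uses batch moments.
bn_fwd <- function(x, p, st, training, momentum = 0.99, eps = 1e-3) {
  d <- dim(x)
  C <- d[4]
  xp <- aperm(x, c(1, 2, 3, 5, 4))
  xm <- matrix(xp, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    st$mean <- momentum * st$mean + (1 - momentum) * mu
    st$var <- momentum * st$var + (1 - momentum) * v
  } else {
    mu <- st$mean
    v <- st$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
  ym <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  y <- aperm(array(ym, dim(xp)), c(1, 2, 3, 5, 4))
  list(y = y, state = st,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, training = training))
}

bn_bwd <- function(cache, p, dy) {
  d <- cache$dims
  C <- d[4]
  dym <- matrix(aperm(dy, c(1, 2, 3, 5, 4)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, p$gamma, "*")
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dxm <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"),
                 2, cache$inv_sd, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$inv_sd, "*")
  }
  dx <- aperm(array(dxm, d[c(1, 2, 3, 5, 4)]), c(1, 2, 3, 5, 4))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) {
    stop("spatial dimensions [", paste(d[1:3], collapse = " x "),
         "] must be even before 2 x 2 x 2 max-pooling")
  }
  r <- cpp_maxpool_fwd(x, d)
  list(y = r$y, argmax = r$argmax, in_dim = d)
}

pool_bwd <- function(cache, dy) {
  cpp_maxpool_bwd(cache$argmax, dy, cache$in_dim)
}

# concatenate two equally shaped feature maps along the channel axis
channel_concat <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], 2L * d[4], d[5]))
  out[, , , seq_len(d[4]), ] <- a
  out[, , , d[4] + seq_len(d[4]), ] <- b
  out
}
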