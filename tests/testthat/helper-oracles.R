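# Independent reference implementations used as oracles.  These are written
# as direct transcriptions of the definitions (explicit loops, no shared code
# with the package internals) and are only ever run on tiny inputs.

# dot-product softmax attention, N x C matrices
oracle_attention <- function(Q, V, use_scale = FALSE) {
  N <- nrow(Q)
  C <- ncol(Q)
  out <- matrix(0, N, C)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * V[j, ])
    if (use_scale) s <- s / sqrt(C)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(N)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# stride-1 zero-padded 3D convolution, x: (X,Y,Z,Cin), w: (k,k,k,Cin,Cout)
oracle_conv3 <- function(x, w, b) {
  d <- dim(x)
  k <- dim(w)[1]
  p <- (k - 1) / 2
  cout <- dim(w)[5]
  y <- array(0, c(d[1:3], cout))
  for (co in seq_len(cout)) {
    y[, , , co] <- b[co]
    for (ci in seq_len(d[4]))
      for (dz in seq_len(k)) for (dy in seq_len(k)) for (dx in seq_len(k))
        for (z in seq_len(d[3])) {
          sz <- z + dz - 1 - p
          if (sz < 1 || sz > d[3]) next
          for (yy in seq_len(d[2])) {
            sy <- yy + dy - 1 - p
            if (sy < 1 || sy > d[2]) next
            for (xx in seq_len(d[1])) {
              sx <- xx + dx - 1 - p
              if (sx < 1 || sx > d[1]) next
              y[xx, yy, z, co] <- y[xx, yy, z, co] +
                x[sx, sy, sz, ci] * w[dx, dy, dz, ci, co]
            }
          }
        }
  }
  y
}

oracle_maxpool <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1:3] %/% 2L, d[4]))
  for (c in seq_len(d[4]))
    for (z in seq_len(d[3] %/% 2)) for (yy in seq_len(d[2] %/% 2))
      for (xx in seq_len(d[1] %/% 2)) {
        y[xx, yy, z, c] <- max(x[(2 * xx - 1):(2 * xx),
                                 (2 * yy - 1):(2 * yy),
                                 (2 * z - 1):(2 * z), c])
      }
  y
}

oracle_elu <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))

# inference batch norm with given running statistics
oracle_bn <- function(x, gamma, beta, mean, var, eps = 1e-3) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[4])) {
    y[, , , c] <- (x[, , , c] - mean[c]) / sqrt(var[c] + eps) * gamma[c] + beta[c]
  }
  y
}

# trilinear resampling with half-pixel centre alignment, explicit loops
oracle_trilinear <- function(grid, target) {
  d <- dim(grid)
  f <- d / target
  out <- array(0, target)
  for (k in seq_len(target[3])) for (j in seq_len(target[2]))
    for (i in seq_len(target[1])) {
      s <- c((i - 0.5) * f[1] - 0.5, (j - 0.5) * f[2] - 0.5,
             (k - 0.5) * f[3] - 0.5)
      s <- pmin(pmax(s, 0), d - 1)
      lo <- pmin(floor(s), d - 1)
      hi <- pmin(lo + 1, d - 1)
      w <- s - lo
      acc <- 0
      for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
        wt <- (if (cx) w[1] else 1 - w[1]) *
          (if (cy) w[2] else 1 - w[2]) *
          (if (cz) w[3] else 1 - w[3])
        acc <- acc + wt * grid[(if (cx) hi[1] else lo[1]) + 1,
                               (if (cy) hi[2] else lo[2]) + 1,
                               (if (cz) hi[3] else lo[3]) + 1]
      }
      out[i, j, k] <- acc
    }
  out
}

# confusion counts and derived metrics by direct tally (AD positive)
oracle_confusion_metrics <- function(truth, predicted) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "AD" && predicted[i] == "AD") tp <- tp + 1L
    if (truth[i] == "CN" && predicted[i] == "AD") fp <- fp + 1L
    if (truth[i] == "AD" && predicted[i] == "CN") fn <- fn + 1L
    if (truth[i] == "CN" && predicted[i] == "CN") tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accuracy = (tp + tn) / length(truth))
}

# AUC as the normalised Mann-Whitney U statistic (pairwise comparison)
oracle_auc_mw <- function(truth, prob) {
  pos <- which(truth == "AD")
  neg <- which(truth == "CN")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (prob[i] > prob[j]) + 0.5 * (prob[i] == prob[j])
  }
  tot / (length(pos) * length(neg))
}

# counts voxels below an intensity threshold (ventricle proxy on noise-free
# phantoms: ventricle is the only low-but-nonzero compartment)
ventricle_voxels <- function(vol, lo = 0.01, hi = 0.3) {
  sum(vol$grid > lo & vol$grid < hi & vol$mask)
}
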