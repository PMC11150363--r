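test_that("configuration invariants are enforced", {
  expect_error(network_config(features = c(8, 8, 16), types = rep("res", 3),
                              input_shape = c(32, 32, 16)), "increasing")
  expect_error(network_config(features = c(4, 8, 16),
                              types = c("res", "att", "res"),
                              input_shape = c(30, 32, 16)), "divisible")
  cfg <- network_config()
  expect_equal(cfg$features, c(8L, 16L, 32L, 64L, 128L))
  expect_equal(cfg$types, c("res", "att", "res", "att", "res"))
})

test_that("default architecture realises the documented shape cascade", {
  cfg <- network_config()  # 64 x 64 x 32 input, 5 blocks
  model <- build_network(cfg, seed = 1)
  xb <- array(rnorm(64 * 64 * 32), c(64, 64, 32, 1, 1))
  r <- brainage:::net_forward(model, xb, sex = 1, keep_cache = TRUE)
  expect_equal(dim(r$cache$block_out), c(2, 2, 1, 128, 1))  # terminal map
  expect_equal(ncol(r$cache$flat), 512)                     # flatten length
  expect_equal(ncol(r$cache$fused), 129)                    # F_l + gender
  expect_length(r$pred, 1)                                  # scalar age
  expect_length(r$features, 128)
})

test_that("the reduced test-scale architecture flattens at 4 x 4 x 2", {
  cfg <- network_config(features = c(4, 8, 16), types = c("res", "att", "res"),
                        input_shape = c(32, 32, 16))
  model <- build_network(cfg, seed = 1)
  xb <- array(rnorm(32 * 32 * 16), c(32, 32, 16, 1, 1))
  r <- brainage:::net_forward(model, xb, sex = 0, keep_cache = TRUE)
  expect_equal(dim(r$cache$block_out), c(4, 4, 2, 16, 1))
  expect_equal(ncol(r$cache$flat), 4 * 4 * 2 * 16)
})

test_that("block outputs halve each spatial dimension", {
  cfg <- tiny_config()
  model <- build_network(cfg, seed = 2)
  xb <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1, 1))
  r <- brainage:::net_forward(model, xb, 0, keep_cache = TRUE)
  dims <- lapply(r$cache$blocks, function(cc) dim(cc$pl$y)[1:3])
  expect_equal(dims[[1]], c(8, 8, 4))
  expect_equal(dims[[2]], c(4, 4, 2))
  expect_equal(dims[[3]], c(2, 2, 1))
})

test_that("two builds with the same seed are identical", {
  cfg <- tiny_config()
  a <- build_network(cfg, seed = 5)
  b <- build_network(cfg, seed = 5)
  expect_identical(a$params, b$params)
  c <- build_network(cfg, seed = 6)
  expect_false(identical(a$params, c$params))
})

test_that("residual block with zeroed residual path equals its shortcut", {
  cfg <- network_config(features = 4, types = "res", input_shape = c(8, 8, 4),
                        dense_units = 4L)
  bp <- build_network(cfg, seed = 3)$params$blocks[[1]]
  bp$conv2$w[] <- 0   # F(x) = BN(0) = 0 under unit-variance running stats
  bp$conv2$b[] <- 0
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  got <- res_block_forward(x, bp)
  s <- oracle_conv3(x, bp$shortcut$w, bp$shortcut$b)
  want <- oracle_maxpool(oracle_elu(s))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("residual block matches a dense explicit-loop composition", {
  cfg <- network_config(features = 3, types = "res", input_shape = c(4, 4, 2),
                        dense_units = 2L)
  bp <- build_network(cfg, seed = 9)$params$blocks[[1]]
  x <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  got <- res_block_forward(x, bp)
  f <- length(bp$bn1$gamma)
  bn0 <- function(z, bn) oracle_bn(z, bn$gamma, bn$beta, rep(0, f), rep(1, f))
  y1 <- oracle_elu(bn0(oracle_conv3(x, bp$conv1$w, bp$conv1$b), bp$bn1))
  y2 <- bn0(oracle_conv3(y1, bp$conv2$w, bp$conv2$b), bp$bn2)
  s <- oracle_conv3(x, bp$shortcut$w, bp$shortcut$b)
  want <- oracle_maxpool(oracle_elu(s + y2))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("odd spatial dimensions are rejected before any computation", {
  cfg <- network_config(features = 4, types = "res", input_shape = c(8, 8, 4),
                        dense_units = 4L)
  bp <- build_network(cfg, seed = 3)$params$blocks[[1]]
  expect_error(res_block_forward(array(0, c(7, 8, 4, 1)), bp), "even")
  ap <- build_network(network_config(features = 4, types = "att",
                                     input_shape = c(8, 8, 4),
                                     dense_units = 4L),
                      seed = 3)$params$blocks[[1]]
  expect_error(attention_block_forward(array(0, c(8, 5, 4, 1)), ap), "even")
})

test_that("attention matches the explicit-loop oracle (incl. scaling, chunking)", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(2:8, 1)
    C <- sample(1:4, 1)
    Q <- matrix(rnorm(N * C), N, C)
    V <- matrix(rnorm(N * C), N, C)
    for (us in c(FALSE, TRUE)) {
      want <- oracle_attention(Q, V, us)
      expect_equal(attention_forward(Q, V, use_scale = us), want,
                   tolerance = 1e-10)
      expect_equal(attention_forward(Q, V, use_scale = us, chunk = 2), want,
                   tolerance = 1e-10)
    }
  }
})

test_that("attention outputs stay in the convex hull of the value rows", {
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    C <- sample(1:3, 1)
    Q <- matrix(rnorm(N * C, sd = 3), N, C)
    V <- matrix(rnorm(N * C), N, C)
    out <- attention_forward(Q, V)
    for (c in seq_len(C)) {
      expect_true(all(out[, c] >= min(V[, c]) - 1e-10))
      expect_true(all(out[, c] <= max(V[, c]) + 1e-10))
    }
  }
})

test_that("identical value rows collapse attention to that vector", {
  v <- c(1.5, -2, 0.25)
  V <- matrix(v, nrow = 5, ncol = 3, byrow = TRUE)
  Q <- matrix(rnorm(15, sd = 10), 5, 3)
  out <- attention_forward(Q, V)
  expect_equal(out, V, tolerance = 1e-12)
})

test_that("boosting one value row concentrates attention onto it", {
  set.seed(13)
  N <- 4; C <- 2
  Q <- matrix(1, N, C)
  V <- matrix(rnorm(N * C), N, C)
  V[2, ] <- c(5, 5)    # large positive score against all-ones queries
  out1 <- attention_forward(Q, V)
  V2 <- V; V2[2, ] <- c(15, 15)
  out2 <- attention_forward(Q, V2)
  # outputs move towards the boosted row as its score grows
  d1 <- sqrt(rowSums((out1 - matrix(V[2, ], N, C, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((out2 - matrix(V2[2, ], N, C, byrow = TRUE))^2))
  expect_true(all(d2 < d1 + 1e-9))
})

test_that("attention block equals the composition of its five steps", {
  cfg <- network_config(features = 2, types = "att", input_shape = c(4, 4, 2),
                        dense_units = 2L)
  ap <- build_network(cfg, seed = 21)$params$blocks[[1]]
  x <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  got <- attention_block_forward(x, ap)

  f <- length(ap$bn$gamma)
  Q <- oracle_conv3(x, ap$q$w, ap$q$b)
  V <- oracle_conv3(x, ap$v$w, ap$v$b)
  att <- array(oracle_attention(matrix(Q, ncol = f), matrix(V, ncol = f)),
               dim(Q))
  Con <- array(c(Q, att), c(dim(Q)[1:3], 2 * f))
  P <- oracle_conv3(Con, ap$proj$w, ap$proj$b)
  B <- oracle_bn(P, ap$bn$gamma, ap$bn$beta, rep(0, f), rep(1, f))
  want <- oracle_maxpool(oracle_elu(B))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("constant value embeddings reduce the block to a position-independent augmentation", {
  cfg <- network_config(features = 2, types = "att", input_shape = c(4, 4, 2),
                        dense_units = 2L)
  ap <- build_network(cfg, seed = 22)$params$blocks[[1]]
  ap$v$w[] <- 0
  ap$v$b <- c(0.7, -0.3)        # V constant over positions
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  got <- attention_block_forward(x, ap)
  # attention output is the constant V row everywhere, independent of Q
  f <- 2
  Q <- oracle_conv3(x, ap$q$w, ap$q$b)
  att <- array(rep(ap$v$b, each = prod(dim(x)[1:3])), c(dim(x)[1:3], f))
  Con <- array(c(Q, att), c(dim(x)[1:3], 2 * f))
  P <- oracle_conv3(Con, ap$proj$w, ap$proj$b)
  B <- oracle_bn(P, ap$bn$gamma, ap$bn$beta, rep(0, f), rep(1, f))
  want <- oracle_maxpool(oracle_elu(B))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("inference forward is deterministic and exposes F_l", {
  cfg <- tiny_config()
  model <- build_network(cfg, seed = 4)
  p <- phantom_params(shape = c(16, 16, 8), noise_sd = 0)
  v <- normalize_intensity(extract_brain(make_phantom(40, 1, p, 1),
                                         mask = make_phantom(40, 1, p, 1)$mask))
  a <- model_forward(model, v, sex = 1)
  b <- model_forward(model, v, sex = 1)
  expect_identical(a, b)
  expect_length(a$features, cfg$dense_units)
  expect_error(model_forward(model, array(0, c(8, 8, 8)), 1), "input shape")
})

test_that("zeroing the gender weight makes predictions sex-invariant", {
  cfg <- tiny_config()
  model <- build_network(cfg, seed = 4)
  xb <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  with_g <- abs(model_forward(model, xb, 0)$age -
                  model_forward(model, xb, 1)$age)
  expect_gt(with_g, 0)
  model$params$out_w[cfg$dense_units + 1, 1] <- 0
  expect_equal(model_forward(model, xb, 0)$age,
               model_forward(model, xb, 1)$age, tolerance = 1e-12)
})

test_that("model checkpoints round-trip", {
  model <- build_network(tiny_config(), seed = 4)
  p <- tempfile(fileext = ".rds")
  save_model(model, p)
  back <- load_model(p)
  expect_identical(back$params, model$params)
  saveRDS(1:3, p)
  expect_error(load_model(p), "not a brainage model")
})
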