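phantom32 <- function(...) {
  p <- phantom_params(shape = c(32, 32, 16), noise_sd = 0, bias_amplitude = 0, ...)
  list(params = p, vol = make_phantom(55, 1, p, seed = 3))
}

test_that("mask application zeroes background and shell exactly", {
  f <- phantom32()
  out <- extract_brain(f$vol, mask = f$vol$mask)
  expect_true(all(out$grid[!f$vol$mask] == 0))
  expect_identical(out$grid[f$vol$mask], f$vol$grid[f$vol$mask])
  expect_identical(out$mask, f$vol$mask)
  expect_error(extract_brain(f$vol, mask = array(TRUE, c(8, 8, 8))),
               "does not match")
})

test_that("threshold fallback recovers the brain mask (Dice >= 0.90)", {
  f <- phantom32()
  out <- extract_brain(f$vol)                 # no mask given
  expect_gte(dice_coefficient(out$mask, f$vol$mask), 0.90)
  # with mild noise it still works
  pn <- phantom_params(shape = c(32, 32, 16), noise_sd = 0.02)
  vn <- make_phantom(55, 1, pn, seed = 3)
  outn <- extract_brain(volume_image(vn$grid))
  expect_gte(dice_coefficient(outn$mask, vn$mask), 0.90)
})

test_that("degenerate extraction inputs raise extraction errors", {
  expect_error(extract_brain(volume_image(array(0, c(8, 8, 8)))),
               "extraction failed")
  tool <- function(v) array(TRUE, c(2, 2, 2))
  f <- phantom32()
  expect_error(extract_brain(volume_image(f$vol$grid), tool = tool),
               "wrong shape")
})

test_that("bias correction leaves an unbiased phantom nearly unchanged", {
  f <- phantom32()
  v <- extract_brain(f$vol, mask = f$vol$mask)
  out <- correct_bias(v, order = 2)
  rel <- abs(out$grid[v$mask] - v$grid[v$mask]) / v$grid[v$mask]
  expect_lt(max(rel), 0.02)
})

test_that("a known order-2 multiplicative field is removed to <= 5%", {
  p <- phantom_params(shape = c(32, 32, 16), noise_sd = 0, bias_amplitude = 0.3)
  clean <- make_phantom(55, 1, phantom_params(shape = c(32, 32, 16),
                                              noise_sd = 0), seed = 3)
  biased <- make_phantom(55, 1, p, seed = 3)   # same geometry, field applied
  v <- extract_brain(biased, mask = biased$mask)
  out <- correct_bias(v, order = 2)
  rel <- abs(out$grid[v$mask] - clean$grid[v$mask]) / clean$grid[v$mask]
  expect_lte(max(rel), 0.05)
})

test_that("order-0 correction is a pure global rescale", {
  p <- phantom_params(shape = c(16, 16, 8), noise_sd = 0, bias_amplitude = 0.3)
  v <- make_phantom(40, 0, p, seed = 5)
  v <- extract_brain(v, mask = v$mask)
  out <- correct_bias(v, order = 0)
  ratio <- out$grid[v$mask] / v$grid[v$mask]
  expect_lt(diff(range(ratio)), 1e-12)
  expect_equal(mean(out$grid[v$mask]), mean(v$grid[v$mask]))
})

test_that("bias correction validates inputs and honours the external hook", {
  f <- phantom32()
  expect_error(correct_bias(volume_image(f$vol$grid)), "mask")
  hook <- function(vol, mask) volume_image(vol$grid * 2, vol$spacing, mask)
  out <- correct_bias(extract_brain(f$vol, f$vol$mask), n4_hook = hook)
  expect_equal(out$grid, extract_brain(f$vol, f$vol$mask)$grid * 2)
})

test_that("resampling hits the target grid and preserves constants", {
  g <- array(3.5, c(40, 24, 20))
  out <- resize_volume(volume_image(g, spacing = c(1, 2, 1)), c(10, 12, 4))
  expect_equal(dim(out$grid), c(10, 12, 4))
  expect_equal(as.vector(out$grid), rep(3.5, 480), tolerance = 1e-9)
  expect_equal(out$spacing, c(4, 4, 5))  # physical extent preserved
  expect_error(resize_volume(volume_image(g), c(0, 4, 4)), ">= 2")
})

test_that("a large isotropic head volume resamples to the network grid", {
  g <- array(0, c(256, 256, 256))
  g[64:192, 64:192, 64:192] <- 1
  out <- resize_volume(volume_image(g), c(64, 64, 32))
  expect_equal(dim(out$grid), c(64, 64, 32))
  expect_gt(mean(out$grid), 0.05)
})

test_that("trilinear resampling matches an explicit-loop oracle", {
  ramp <- array(rep(seq_len(4), times = 16), c(4, 4, 4))  # ramp along x
  got <- resize_volume(volume_image(ramp), c(2, 2, 2), antialias = FALSE)
  expect_equal(got$grid, oracle_trilinear(ramp, c(2, 2, 2)), tolerance = 1e-6)

  set.seed(31)
  g <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  for (target in list(c(3, 4, 2), c(7, 6, 8), c(2, 2, 2))) {
    got <- resize_volume(volume_image(g), target, antialias = FALSE)
    expect_equal(got$grid, oracle_trilinear(g, target), tolerance = 1e-6)
  }
})

test_that("mask resampling is nearest-neighbour and stays logical", {
  f <- phantom32()
  v <- extract_brain(f$vol, f$vol$mask)
  out <- resize_volume(v, c(16, 16, 8))
  expect_type(out$mask, "logical")
  expect_equal(dim(out$mask), c(16, 16, 8))
  expect_gt(sum(out$mask), 0)
})

test_that("normalisation z-scores inside the mask and is idempotent", {
  f <- phantom32()
  v <- extract_brain(f$vol, f$vol$mask)
  n1 <- normalize_intensity(v)
  expect_lt(abs(mean(n1$grid[v$mask])), 1e-6)
  expect_lt(abs(sd(n1$grid[v$mask]) - 1), 1e-6)
  expect_true(all(n1$grid[!v$mask] == 0))
  n2 <- normalize_intensity(n1)
  expect_equal(n2$grid, n1$grid, tolerance = 1e-6)

  flat <- volume_image(array(5, c(8, 8, 8)), mask = array(TRUE, c(8, 8, 8)))
  expect_warning(z <- normalize_intensity(flat), "zero variance")
  expect_true(all(z$grid == 0))
})

test_that("the pipeline composes its stages in fixed order", {
  pn <- phantom_params(shape = c(32, 32, 16), noise_sd = 0.01)
  v <- make_phantom(60, 0, pn, seed = 7)
  cfg <- preprocess_config(mask = v$mask, bias = FALSE,
                           target_shape = c(16, 16, 8))
  out <- preprocess_pipeline(v, cfg)
  expect_equal(dim(out$grid), c(16, 16, 8))
  expect_lt(abs(mean(out$grid[out$mask])), 1e-6)

  # switch semantics: disabling a stage equals composing without it
  manual <- normalize_intensity(resize_volume(extract_brain(v, v$mask),
                                              c(16, 16, 8)))
  expect_equal(out$grid, manual$grid, tolerance = 1e-12)

  # stage errors carry the stage name
  expect_error(preprocess_pipeline(volume_image(array(0, c(8, 8, 8))),
                                   preprocess_config()),
               "\\[extract_brain\\]")
})

test_that("bias correction moves a biased scan closer to the clean reference", {
  shape <- c(32, 32, 16)
  clean <- make_phantom(55, 1, phantom_params(shape = shape, noise_sd = 0),
                        seed = 3)
  biased <- make_phantom(55, 1, phantom_params(shape = shape, noise_sd = 0,
                                               bias_amplitude = 0.4), seed = 3)
  base <- preprocess_config(mask = clean$mask, bias = FALSE, resize = FALSE)
  with_corr <- preprocess_config(mask = clean$mask, bias = TRUE, resize = FALSE)
  ref <- preprocess_pipeline(clean, base)
  got_corr <- preprocess_pipeline(biased, with_corr)
  got_raw <- preprocess_pipeline(biased, base)
  m <- clean$mask
  l2 <- function(a, b) sqrt(sum((a$grid[m] - b$grid[m])^2))
  expect_lt(l2(got_corr, ref), l2(got_raw, ref))
})
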