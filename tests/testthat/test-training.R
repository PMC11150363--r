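test_that("regression metrics satisfy their closed forms", {
  ages <- c(30, 45, 60, 75, 20)
  m <- regression_metrics(ages, ages)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$pcc, 1)
  expect_equal(m$srcc, 1)
  expect_equal(m$r2, 1)

  m2 <- regression_metrics(ages, ages + 2)
  expect_equal(m2$mae, 2)
  expect_equal(m2$rmse, 2)
  expect_equal(m2$pcc, 1)
  expect_lt(m2$r2, 1)
  expect_equal(m2$ci95, c(2, 2))  # zero-variance signed error
})

test_that("metrics match an independently coded formula oracle", {
  truth <- c(23.0, 41.5, 58.2, 66.0, 79.9)
  pred <- c(25.1, 39.0, 60.0, 61.5, 83.2)
  m <- regression_metrics(truth, pred)
  err <- pred - truth
  expect_equal(m$mae, sum(abs(err)) / 5, tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(sum(err^2) / 5), tolerance = 1e-9)
  expect_equal(m$pcc,
               sum((truth - mean(truth)) * (pred - mean(pred))) /
                 sqrt(sum((truth - mean(truth))^2) * sum((pred - mean(pred))^2)),
               tolerance = 1e-9)
  expect_equal(m$srcc, cor(rank(truth), rank(pred)), tolerance = 1e-9)
  expect_equal(m$r2, 1 - sum(err^2) / sum((truth - mean(truth))^2),
               tolerance = 1e-9)
  # t-based interval of the mean signed error
  se <- sd(err) / sqrt(5)
  expect_equal(m$ci95, mean(err) + c(-1, 1) * qt(0.975, 4) * se,
               tolerance = 1e-9)
})

test_that("mae <= rmse and srcc is invariant to monotone transforms", {
  set.seed(17)
  for (i in 1:20) {
    t <- runif(10, 20, 80)
    p <- t + rnorm(10, sd = 5)
    m <- regression_metrics(t, p)
    expect_lte(m$mae, m$rmse + 1e-12)
    m2 <- regression_metrics(t, exp(p / 20))     # strictly increasing
    expect_equal(m$srcc, m2$srcc, tolerance = 1e-12)
  }
})

test_that("constant predictions yield NA correlation with a warning", {
  expect_warning(m <- regression_metrics(c(30, 40, 50), rep(44, 3)),
                 "constant")
  expect_true(is.na(m$pcc))
  expect_true(is.na(m$srcc))
})

test_that("zero learning rate leaves parameters untouched", {
  ds <- tiny_dataset(n = 6)
  model <- build_network(tiny_config(), seed = 1)
  before <- model$params
  trained <- train_network(model, ds, spec = train_spec(learning_rate = 0,
                                                        epochs = 2, seed = 2))
  expect_equal(trained$params, before, tolerance = 1e-15)
  expect_equal(nrow(trained$history), 2)
})

test_that("training with a fixed seed reproduces the loss history exactly", {
  ds <- tiny_dataset(n = 8)
  val <- tiny_dataset(n = 4, ages = c(25, 45, 65, 78), seed = 50)
  spec <- train_spec(epochs = 3, seed = 9, batch_size = 4)
  a <- train_network(build_network(tiny_config(), seed = 3), ds, val, spec)
  b <- train_network(build_network(tiny_config(), seed = 3), ds, val, spec)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("a few epochs reduce the validation loss on phantoms", {
  ds <- tiny_dataset(n = 16, noise_sd = 0.01,
                     ages = rep(seq(20, 80, length.out = 8), 2))
  val <- tiny_dataset(n = 6, noise_sd = 0.01, seed = 77)
  model <- build_network(tiny_config(dense_units = 16L), seed = 5)
  trained <- train_network(model, ds, val, train_spec(epochs = 6, seed = 6))
  h <- trained$history
  expect_lt(min(h$val_loss), h$val_loss[1])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("the best-validation parameters are the ones retained", {
  ds <- tiny_dataset(n = 8, noise_sd = 0.01)
  val <- tiny_dataset(n = 4, seed = 33)
  trained <- train_network(build_network(tiny_config(), seed = 8), ds, val,
                           train_spec(epochs = 4, seed = 8))
  best_epoch_loss <- min(trained$history$val_loss)
  expect_equal(brainage:::.dataset_loss(trained, val, 8L), best_epoch_loss,
               tolerance = 1e-9)
})

test_that("degenerate training inputs abort with diagnostics", {
  ds <- tiny_dataset(n = 4)
  model <- build_network(tiny_config(), seed = 1)
  model$params$dense_w[] <- 1e200   # forward pass overflows
  expect_error(train_network(model, ds, spec = train_spec(epochs = 1, seed = 1)),
               "non-finite")
  expect_error(train_spec(epochs = 0), "epochs")
  expect_error(train_spec(learning_rate = -1), "learning_rate")
})
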