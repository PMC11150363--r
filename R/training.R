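#' Training specification
#'
#' Defaults follow the optimiser/loss schedule the architecture was designed
#' around: Adam with learning rate 0.0007, mean-squared-error loss, 100
#' epochs (no early stopping; the best-validation-loss parameters are
#' checkpointed), batch size 8.
#'
#' @param learning_rate Adam step size (>= 0; 0 performs no updates).
#' @param epochs number of epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param seed integer seed governing shuffling and dropout; a fixed seed
#'   reproduces the loss history exactly on one device.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 7e-4, epochs = 100L, batch_size = 8L,
                       seed = 1L, beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_spec")
}

#' Assemble an in-memory training dataset
#'
#' Stacks preprocessed volumes with their ages and sex codes.  Volumes may be
#' [volume_image]s or bare 3D arrays; all must share one shape.
#'
#' @param volumes list of volumes.
#' @param age numeric ages in years, one per volume.
#' @param sex integer codes in `{0, 1}`, one per volume.
#' @param diagnosis optional `CN`/`AD` labels carried along for downstream
#'   classification.
#' @return An object of class `brainage_dataset` with the stacked `(X, Y, Z,
#'   1, n)` array in `$x`.
#' @export
brainage_dataset <- function(volumes, age, sex, diagnosis = NULL) {
  n <- length(volumes)
  stopifnot(n >= 1, length(age) == n, length(sex) == n)
  grids <- lapply(volumes, function(v) if (inherits(v, "volume_image")) v$grid else v)
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) identical(dim(g), d), logical(1)))) {
    stop("all volumes must share one shape")
  }
  x <- array(0, c(d, 1L, n))
  for (i in seq_len(n)) x[, , , 1L, i] <- grids[[i]]
  structure(list(x = x, age = as.numeric(age), sex = as.integer(sex),
                 diagnosis = diagnosis, n = n),
            class = "brainage_dataset")
}

#' Build a dataset from a cohort
#'
#' Reads (or takes) each scan, runs the preprocessing pipeline when a config
#' is given, and stacks the result in manifest order.
#'
#' @param cohort a [cohort].
#' @param volumes optional list of volumes aligned with the cohort records
#'   (required when `scan_path` entries are `mem://` placeholders).
#' @param cfg optional [preprocess_config] applied to every scan.
#' @return A [brainage_dataset].
#' @export
build_dataset <- function(cohort, volumes = NULL, cfg = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  r <- cohort$records
  if (is.null(volumes)) {
    if (any(startsWith(r$scan_path, "mem://"))) {
      stop("cohort holds in-memory scan ids; pass `volumes`")
    }
    volumes <- lapply(r$scan_path, read_volume)
  }
  stopifnot(length(volumes) == nrow(r))
  if (!is.null(cfg)) volumes <- lapply(volumes, preprocess_pipeline, cfg = cfg)
  brainage_dataset(volumes, r$age, r$sex, r$diagnosis)
}

.dataset_slice <- function(data, idx) {
  list(x = data$x[, , , , idx, drop = FALSE],
       age = data$age[idx], sex = data$sex[idx])
}

.flatten_params <- function(p) unlist(p, use.names = FALSE)

.unflatten_params <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  rec(skel)
}

.batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

# inference-mode MSE over a dataset, evaluated in batches
.dataset_loss <- function(model, data, batch_size) {
  tot <- 0
  for (idx in .batch_indices(data$n, batch_size)) {
    b <- .dataset_slice(data, idx)
    r <- net_forward(model, b$x, b$sex, training = FALSE)
    tot <- tot + sum((r$pred - b$age)^2)
  }
  tot / data$n
}

#' Train the network
#'
#' Mini-batch Adam on the mean-squared-error between predicted and
#' chronological age, plus the configured L2 penalty on the dense layer.
#' Per-epoch training and validation losses are recorded in `$history`; the
#' parameters (and batch-norm statistics) achieving the best validation loss
#' are retained.  Fully reproducible for a fixed `spec$seed` on one device.
#'
#' @param model an untrained (or partially trained) `brainage_model`.
#' @param data training [brainage_dataset].
#' @param val_data validation [brainage_dataset]; when `NULL`, the training
#'   loss drives checkpoint selection.
#' @param spec a [train_spec].
#' @param verbose print per-epoch losses.
#' @return The trained `brainage_model`.
#' @export
train_network <- function(model, data, val_data = NULL, spec = train_spec(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "brainage_model"),
            inherits(data, "brainage_dataset"), inherits(spec, "train_spec"))
  if (data$n < 1) stop("training dataset is empty")
  cfg <- model$config
  with_seed(spec$seed, {
    theta <- .flatten_params(model$params)
    m <- numeric(length(theta))
    v <- numeric(length(theta))
    tstep <- 0L
    best <- list(loss = Inf, params = model$params, state = model$state)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample(data$n)
      epoch_loss <- 0
      for (idx in .batch_indices(data$n, spec$batch_size)) {
        b <- .dataset_slice(data, perm[idx])
        fw <- net_forward(model, b$x, b$sex, training = TRUE, keep_cache = TRUE)
        model$state <- fw$state
        resid <- fw$pred - b$age
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (diverged; lower the learning rate)")
        }
        epoch_loss <- epoch_loss + sum(resid^2)
        bw <- net_backward(model, fw$cache, 2 * resid / length(resid))
        g <- bw$grads
        g$dense_w <- g$dense_w + 2 * cfg$dense_l2 * model$params$dense_w
        gv <- .flatten_params(g)
        tstep <- tstep + 1L
        m <- spec$beta1 * m + (1 - spec$beta1) * gv
        v <- spec$beta2 * v + (1 - spec$beta2) * gv * gv
        mhat <- m / (1 - spec$beta1^tstep)
        vhat <- v / (1 - spec$beta2^tstep)
        theta <- theta - spec$learning_rate * mhat / (sqrt(vhat) + spec$adam_eps)
        model$params <- .unflatten_params(theta, model$params)
      }
      train_loss <- epoch_loss / data$n
      val_loss <- if (!is.null(val_data)) {
        .dataset_loss(model, val_data, spec$batch_size)
      } else train_loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, state = model$state)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %8.3f  val MSE %8.3f",
                        epoch, train_loss, val_loss))
      }
    }
    model$params <- best$params
    model$state <- best$state
    model$history <- history
    model$training_seed <- spec$seed
    model$trained <- TRUE
    model
  })
}

#' Predict ages for a dataset
#'
#' Inference-mode batched forward pass.
#'
#' @param model a `brainage_model`.
#' @param data a [brainage_dataset].
#' @param batch_size evaluation batch size.
#' @return Numeric vector of predicted ages, one per scan.
#' @export
predict_ages <- function(model, data, batch_size = 16L) {
  stopifnot(inherits(model, "brainage_model"), inherits(data, "brainage_dataset"))
  out <- numeric(data$n)
  for (idx in .batch_indices(data$n, batch_size)) {
    b <- .dataset_slice(data, idx)
    out[idx] <- net_forward(model, b$x, b$sex, training = FALSE)$pred
  }
  out
}

#' Regression quality metrics
#'
#' Per-scan metrics on (chronological, predicted) age pairs: mean absolute
#' error, root-mean-squared error, Pearson and Spearman correlations,
#' coefficient of determination, and the t-based 95% confidence interval of
#' the mean signed error.  `mae <= rmse` always; constant predictions make
#' the correlations undefined (`NA` with a warning).
#'
#' @param truth chronological ages (years).
#' @param predicted predicted brain ages (years).
#' @return An object of class `regression_metrics`.
#' @export
regression_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 2)
  err <- predicted - truth
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  if (stats::sd(predicted) == 0 || stats::sd(truth) == 0) {
    warning("constant predictions or ages: correlation undefined")
    pcc <- NA_real_
    srcc <- NA_real_
  } else {
    pcc <- stats::cor(truth, predicted)
    srcc <- stats::cor(truth, predicted, method = "spearman")
  }
  r2 <- 1 - sum(err^2) / sum((truth - mean(truth))^2)
  ci95 <- if (stats::sd(err) == 0) c(mean(err), mean(err)) else {
    as.numeric(stats::t.test(err)$conf.int)
  }
  structure(list(mae = mae, rmse = rmse, pcc = pcc, srcc = srcc, r2 = r2,
                 ci95 = ci95, n = length(truth)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf(paste0("Regression metrics on %d scans:\n",
                     "  MAE  %6.3f years\n  RMSE %6.3f years\n",
                     "  PCC  %6.3f   SRCC %6.3f   R2 %6.3f\n",
                     "  95%% CI of mean signed error: [%.3f, %.3f]\n"),
              x$n, x$mae, x$rmse, x$pcc, x$srcc, x$r2, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Evaluate a model on a test dataset
#'
#' @param model a trained `brainage_model`.
#' @param data a [brainage_dataset] with at least 2 scans.
#' @return A [regression_metrics].
#' @export
evaluate_model <- function(model, data) {
  if (data$n < 2) stop("need at least 2 test scans")
  regression_metrics(data$age, predict_ages(model, data))
}
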