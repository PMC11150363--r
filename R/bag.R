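#' Brain-age gap (BAG) and its use as an Alzheimer's biomarker
#'
#' The brain-age gap is the predicted brain age minus the chronological age.
#' Neurodegeneration appears as accelerated brain aging, so AD subjects show
#' systematically larger gaps than cognitively normal subjects; the gap alone
#' is used here as a one-dimensional feature for binary AD-vs-CN
#' classification by four base classifiers (logistic regression, SVM,
#' AdaBoost, XGBoost) combined by majority voting.
#'
#' @name bag
NULL

#' Compute brain-age gaps
#'
#' @param chronological chronological ages (years).
#' @param brain_age predicted brain ages (years).
#' @return `brain_age - chronological`, elementwise, order preserved.
#' @examples
#' compute_bag(75.0, 77.6)  # 2.6
#' @export
compute_bag <- function(chronological, brain_age) {
  stopifnot(length(chronological) == length(brain_age),
            all(is.finite(chronological)), all(is.finite(brain_age)))
  brain_age - chronological
}

# Discrete (SAMME) AdaBoost with depth-1 rpart stumps on the 1-D BAG feature.
.fit_adaboost <- function(x, y01, n_rounds = 50L) {
  n <- length(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(x = x, y = factor(y01, levels = c(0, 1)))
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ x, data = df, weights = w * n,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       xval = 0))
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != y01))
    if (err <= 1e-12) {  # perfect stump: take it with a large finite weight
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break  # no better than chance under current weights
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # degenerate: fall back to the class prior
    return(structure(list(stumps = list(), alphas = numeric(0),
                          prior = mean(y01)), class = "adaboost_stumps"))
  }
  structure(list(stumps = stumps, alphas = alphas, prior = mean(y01)),
            class = "adaboost_stumps")
}

.predict_adaboost <- function(model, x) {
  if (!length(model$stumps)) return(rep(model$prior, length(x)))
  df <- data.frame(x = x)
  score <- numeric(length(x))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(model$stumps[[m]], df, type = "class")))
    score <- score + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * score))  # margin -> probability (logistic link)
}

#' Fit the four-classifier BAG ensemble
#'
#' Fits logistic regression, a radial-kernel SVM, AdaBoost (decision stumps)
#' and XGBoost on the one-dimensional brain-age-gap feature, with AD as the
#' positive class.  Deterministic for a fixed seed.
#'
#' @param bag numeric brain-age gaps (years).
#' @param diagnosis `CN`/`AD` labels, both classes present.
#' @param seed integer seed.
#' @return An object of class `bag_ensemble`.
#' @export
fit_bag_classifiers <- function(bag, diagnosis, seed = 1L) {
  stopifnot(length(bag) == length(diagnosis))
  y <- factor(as.character(diagnosis), levels = c("CN", "AD"))
  if (anyNA(y)) stop("diagnosis labels must be CN or AD")
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; need both CN and AD")
  }
  y01 <- as.integer(y == "AD")
  xmat <- matrix(bag, ncol = 1, dimnames = list(NULL, "bag"))
  with_seed(seed, {
    lr <- suppressWarnings(
      stats::glm(y01 ~ bag, family = stats::binomial(), data = data.frame(bag = bag)))
    svm <- e1071::svm(x = xmat, y = y, kernel = "radial", probability = TRUE)
    ada <- .fit_adaboost(bag, y01)
    xgb <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2, eta = 0.3,
                    nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(xmat, label = y01, nthread = 1),
      nrounds = 50)
    structure(list(lr = lr, svm = svm, ada = ada, xgb = xgb, seed = seed),
              class = "bag_ensemble")
  })
}

# n x 4 matrix of per-classifier P(AD)
.base_probs <- function(model, bag) {
  xmat <- matrix(bag, ncol = 1, dimnames = list(NULL, "bag"))
  p_lr <- as.numeric(stats::predict(model$lr, data.frame(bag = bag),
                                    type = "response"))
  sv <- stats::predict(model$svm, xmat, probability = TRUE)
  p_svm <- attr(sv, "probabilities")[, "AD"]
  p_ada <- .predict_adaboost(model$ada, bag)
  p_xgb <- as.numeric(stats::predict(model$xgb,
                                     xgboost::xgb.DMatrix(xmat, nthread = 1)))
  cbind(lr = p_lr, svm = unname(p_svm), ada = p_ada, xgb = p_xgb)
}

# Majority vote over base P(AD) columns; 2-2 ties break on the mean
# probability versus 0.5.  Returns labels and the mean-probability score.
ensemble_vote <- function(base_probs) {
  votes <- base_probs > 0.5
  n_ad <- rowSums(votes)
  mean_p <- rowMeans(base_probs)
  label <- ifelse(n_ad > ncol(base_probs) / 2, "AD",
                  ifelse(n_ad < ncol(base_probs) / 2, "CN",
                         ifelse(mean_p > 0.5, "AD", "CN")))
  list(label = factor(label, levels = c("CN", "AD")), prob = mean_p,
       votes = votes)
}

#' Predict with the majority-voting ensemble
#'
#' Each sample's label is the majority of the four base votes; 2-2 ties are
#' broken by the mean of the four predicted AD probabilities versus 0.5
#' (strictly greater -> AD).  The ensemble probability used for the ROC curve
#' is the mean base probability.
#'
#' @param model a `bag_ensemble` from `fit_bag_classifiers()`.
#' @param bag brain-age gaps to classify.
#' @return A list with `label` (factor CN/AD), `prob` (mean P(AD)),
#'   `base_probs` (n x 4 matrix) and `votes`.
#' @export
ensemble_predict <- function(model, bag) {
  stopifnot(inherits(model, "bag_ensemble"))
  bp <- .base_probs(model, bag)
  v <- ensemble_vote(bp)
  list(label = v$label, prob = v$prob, base_probs = bp, votes = v$votes)
}

#' Binary classification metrics with ROC/AUC
#'
#' AD is the positive class.  Confusion counts are tallied directly;
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean) and
#' accuracy `(TP+TN)/n` follow from the counts.  The ROC curve is a
#' threshold sweep over the scores and the AUC its trapezoid integral.
#' Zero denominators yield `NA` with a warning.
#'
#' @param truth true `CN`/`AD` labels.
#' @param predicted predicted `CN`/`AD` labels.
#' @param probabilities P(AD) scores for the ROC sweep (optional).
#' @return An object of class `classifier_report` with `confusion`,
#'   `precision`, `recall`, `f1`, `accuracy`, `roc` (data.frame of FPR/TPR)
#'   and `auc`.
#' @export
classification_metrics <- function(truth, predicted, probabilities = NULL) {
  truth <- factor(as.character(truth), levels = c("CN", "AD"))
  predicted <- factor(as.character(predicted), levels = c("CN", "AD"))
  stopifnot(length(truth) == length(predicted), !anyNA(truth), !anyNA(predicted))
  tp <- sum(truth == "AD" & predicted == "AD")
  fp <- sum(truth == "CN" & predicted == "AD")
  fn <- sum(truth == "AD" & predicted == "CN")
  tn <- sum(truth == "CN" & predicted == "CN")
  n <- length(truth)
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) warning("F1 undefined")
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / n
  roc <- NULL
  auc <- NA_real_
  if (!is.null(probabilities)) {
    stopifnot(length(probabilities) == n)
    pos <- truth == "AD"
    np <- sum(pos)
    nn <- n - np
    if (np > 0 && nn > 0) {
      ord <- order(probabilities, decreasing = TRUE)
      tpr <- c(0, cumsum(pos[ord]) / np)
      fpr <- c(0, cumsum(!pos[ord]) / nn)
      # collapse runs of tied scores to single ROC vertices
      keepi <- c(!duplicated(probabilities[ord], fromLast = TRUE), TRUE)
      roc <- data.frame(fpr = fpr[keepi], tpr = tpr[keepi])
      auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
    } else {
      warning("ROC undefined: need both classes present")
    }
  }
  structure(list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, roc = roc, auc = auc, n = n),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("Classifier report (%d samples, AD positive):\n",
                     "  TP %d  FP %d  FN %d  TN %d\n",
                     "  precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n"),
              x$n, x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"], x$precision, x$recall, x$f1, x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f (%d ROC points)\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' Stratified train/test split of BAG samples
#'
#' Holds out `round(test_fraction * n)` samples per diagnosis class.
#'
#' @param diagnosis `CN`/`AD` labels.
#' @param test_fraction held-out fraction (default 0.15).
#' @param seed integer seed.
#' @return Logical vector, `TRUE` for test samples.
#' @export
split_bag_samples <- function(diagnosis, test_fraction = 0.15, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  diagnosis <- as.character(diagnosis)
  test <- logical(length(diagnosis))
  with_seed(seed, {
    for (cl in unique(diagnosis)) {
      idx <- which(diagnosis == cl)
      k <- round(test_fraction * length(idx))
      if (k > 0) test[sample(idx, k)] <- TRUE
    }
  })
  test
}

#' End-to-end AD detection from brain-age gaps
#'
#' Stratified 85/15 train/test split, four-classifier fit on the training
#' gaps, majority-vote prediction on the held-out gaps, and per-classifier
#' plus ensemble metrics.
#'
#' @param bag brain-age gaps (years).
#' @param diagnosis `CN`/`AD` labels.
#' @param test_fraction held-out fraction (default 0.15).
#' @param seed integer seed.
#' @return A list with `model`, `test` (logical hold-out mask), `ensemble`
#'   (a `classifier_report`) and `per_classifier` (named list of reports for
#'   the four base classifiers on the same hold-out).
#' @export
detect_ad <- function(bag, diagnosis, test_fraction = 0.15, seed = 1L) {
  stopifnot(length(bag) == length(diagnosis))
  test <- split_bag_samples(diagnosis, test_fraction, seed)
  model <- fit_bag_classifiers(bag[!test], diagnosis[!test], seed = seed)
  pred <- ensemble_predict(model, bag[test])
  truth <- diagnosis[test]
  per <- lapply(colnames(pred$base_probs), function(nm) {
    p <- pred$base_probs[, nm]
    classification_metrics(truth, ifelse(p > 0.5, "AD", "CN"), p)
  })
  names(per) <- colnames(pred$base_probs)
  ens <- classification_metrics(truth, pred$label, pred$prob)
  list(model = model, test = test, ensemble = ens, per_classifier = per,
       predictions = pred)
}
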