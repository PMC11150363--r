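test_that("brain-age gap is an elementwise difference", {
  expect_equal(compute_bag(75.0, 77.6), 2.6)
  expect_equal(compute_bag(60, 60), 0)
  ch <- c(70, 65, 80)
  ba <- c(72.5, 64.0, 86.0)
  expect_equal(compute_bag(ch, ba), c(2.5, -1.0, 6.0))
  expect_error(compute_bag(c(1, NA), c(2, 3)))
})

test_that("confusion metrics agree with the counting oracle exhaustively (n <= 5)", {
  for (n in 1:5) {
    grid <- expand.grid(rep(list(c("CN", "AD")), 2 * n),
                        stringsAsFactors = FALSE)
    got <- want <- vector("list", nrow(grid))
    for (r in seq_len(nrow(grid))) {
      truth <- unlist(grid[r, 1:n], use.names = FALSE)
      pred <- unlist(grid[r, n + 1:n], use.names = FALSE)
      w <- oracle_confusion_metrics(truth, pred)
      g <- suppressWarnings(classification_metrics(truth, pred))
      want[[r]] <- c(w$tp, w$fp, w$fn, w$tn, w$precision, w$recall, w$accuracy)
      got[[r]] <- c(unname(g$confusion), g$precision, g$recall, g$accuracy)
    }
    expect_equal(got, want)
  }
})

test_that("confusion metrics match the oracle on random size-7/8 inputs", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(7:8, 1)
    truth <- sample(c("CN", "AD"), n, replace = TRUE)
    pred <- sample(c("CN", "AD"), n, replace = TRUE)
    want <- oracle_confusion_metrics(truth, pred)
    got <- suppressWarnings(classification_metrics(truth, pred))
    expect_identical(unname(got$confusion),
                     c(want$tp, want$fp, want$fn, want$tn))
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$accuracy, want$accuracy)
  }
})

test_that("the toy confusion table reproduces its textbook metrics", {
  truth <- c(rep("AD", 5), rep("CN", 5))          # TP 3, FN 2, FP 1, TN 4
  pred <- c("AD", "AD", "AD", "CN", "CN", "AD", "CN", "CN", "CN", "CN")
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m$confusion), c(3, 1, 2, 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.7)
})

test_that("AUC equals the Mann-Whitney statistic and the pROC reference", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    truth <- c("AD", "CN", sample(c("CN", "AD"), n - 2, replace = TRUE))
    prob <- runif(n)                                # tie-free a.s.
    m <- suppressWarnings(
      classification_metrics(truth, ifelse(prob > 0.5, "AD", "CN"), prob))
    expect_equal(m$auc, oracle_auc_mw(truth, prob), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = factor(truth, levels = c("CN", "AD")), predictor = prob,
        direction = "<", quiet = TRUE)))
      expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(31)
  truth <- sample(c("CN", "AD"), 12, replace = TRUE)
  truth[1:2] <- c("AD", "CN")
  prob <- runif(12)
  pred <- ifelse(prob > 0.5, "AD", "CN")
  a <- classification_metrics(truth, pred, prob)$auc
  b <- classification_metrics(truth, pred, plogis(5 * prob - 1))$auc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate predictions produce NA metrics with warnings", {
  truth <- c("AD", "AD", "CN")
  expect_warning(m <- classification_metrics(truth, rep("CN", 3)), "precision")
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_warning(classification_metrics(rep("AD", 3), rep("AD", 3),
                                        c(0.9, 0.8, 0.7)), "ROC")
})

test_that("perfectly separated gaps are classified perfectly by every base learner", {
  set.seed(37)
  bag <- c(rnorm(20, 0, 0.5), rnorm(20, 10, 0.5))
  dx <- rep(c("CN", "AD"), each = 20)
  model <- fit_bag_classifiers(bag, dx, seed = 1)
  pred <- ensemble_predict(model, bag)
  expect_true(all(pred$label == dx))
  train_acc <- apply(pred$base_probs, 2, function(p)
    mean(ifelse(p > 0.5, "AD", "CN") == dx))
  expect_true(all(train_acc == 1))
  # probabilities separate too
  m <- classification_metrics(dx, pred$label, pred$prob)
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
})

test_that("the ensemble carries no signal under label permutation (held out)", {
  set.seed(41)
  bag <- rnorm(120, 3, 2)
  dx <- sample(rep(c("CN", "AD"), each = 60))      # labels independent of bag
  test <- split_bag_samples(dx, 0.3, seed = 2)
  model <- fit_bag_classifiers(bag[!test], dx[!test], seed = 2)
  pred <- ensemble_predict(model, bag[test])
  acc <- mean(pred$label == dx[test])
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("majority voting matches brute-force enumeration of all 2^4 patterns", {
  hi <- 0.9; lo <- 0.1
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (r in seq_len(nrow(pats))) {
    votes <- unlist(pats[r, ])
    probs <- ifelse(votes, hi, lo)
    got <- brainage:::ensemble_vote(matrix(probs, 1, 4))
    n_ad <- sum(votes)
    want <- if (n_ad > 2) "AD" else if (n_ad < 2) "CN"
            else if (mean(probs) > 0.5) "AD" else "CN"
    expect_equal(as.character(got$label), want)
    expect_equal(got$prob, mean(probs))
  }
  # documented tie rules: 2-2 with mean 0.7 -> AD; 2-2 with mean 0.3 -> CN
  tie_hi <- brainage:::ensemble_vote(matrix(c(0.95, 0.95, 0.45, 0.45), 1, 4))
  expect_equal(as.character(tie_hi$label), "AD")
  expect_equal(tie_hi$prob, 0.7)
  tie_lo <- brainage:::ensemble_vote(matrix(c(0.55, 0.55, 0.05, 0.05), 1, 4))
  expect_equal(as.character(tie_lo$label), "CN")
})

test_that("fitting is deterministic per seed on a probe grid", {
  set.seed(43)
  bag <- c(rnorm(30, 1, 2), rnorm(30, 6, 2))
  dx <- rep(c("CN", "AD"), each = 30)
  probe <- seq(-5, 12, by = 0.25)
  a <- ensemble_predict(fit_bag_classifiers(bag, dx, seed = 7), probe)
  b <- ensemble_predict(fit_bag_classifiers(bag, dx, seed = 7), probe)
  expect_identical(a$label, b$label)
  expect_equal(a$base_probs, b$base_probs, tolerance = 1e-12)
})

test_that("single-class training sets are rejected", {
  expect_error(fit_bag_classifiers(rnorm(10), rep("CN", 10), seed = 1),
               "single class")
})

test_that("stratified hold-out respects class proportions", {
  dx <- rep(c("CN", "AD"), c(40, 20))
  test <- split_bag_samples(dx, 0.15, seed = 3)
  expect_equal(sum(test & dx == "CN"), 6)
  expect_equal(sum(test & dx == "AD"), 3)
  expect_identical(test, split_bag_samples(dx, 0.15, seed = 3))
})
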