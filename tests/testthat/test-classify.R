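test_that("fold plans partition the data with balanced, stratified folds", {
  y <- factor(rep(c("b", "m"), each = 20))
  plan <- make_folds(y, k = 10, seed = 3)
  expect_identical(sort(unique(plan$assignments)), 1:10)
  expect_true(all(tabulate(plan$assignments, 10) == 4L))

  # 30/10 split into 10 folds: every fold gets 3 of one class, 1 of the other
  y2 <- factor(rep(c("b", "m"), c(30, 10)))
  plan2 <- make_folds(y2, k = 10, seed = 1)
  for (f in 1:10) {
    fold <- y2[plan2$assignments == f]
    expect_identical(sum(fold == "b"), 3L)
    expect_identical(sum(fold == "m"), 1L)
  }
  expect_error(make_folds(y, k = 50), "exceeds")
  expect_identical(make_folds(y, k = 10, seed = 3)$assignments,
                   plan$assignments)
})

test_that("knn returns the label of an exactly matching training point", {
  set.seed(4)
  Xtr <- matrix(rnorm(40), 20, 2)
  ytr <- factor(rep(c("b", "m"), 10))
  pred <- train_predict("knn", Xtr, ytr, Xtr[3, , drop = FALSE],
                        cfg = list(knn_k = 1))
  expect_identical(as.character(pred), as.character(ytr[3]))
})

test_that("svm with rbf kernel solves the 4-point xor like the dual oracle", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- factor(c("n", "p", "p", "n"))
  y_pm <- ifelse(y == "p", 1, -1)
  # oracle works on the standardized coordinates the classifier sees
  Xs <- scale(X)
  oracle_sign <- xor_svm_oracle(Xs, y_pm, sigma = 0.5, C = 100)
  pred <- train_predict("svm", X, y, X, cfg = list(sigma = 0.5, cost = 100))
  expect_identical(ifelse(pred == "p", 1, -1), oracle_sign)
})

test_that("pseudoquadratic discriminant separates two spherical gaussians", {
  errs <- sapply(1:10, function(sd) {
    set.seed(sd)
    make <- function(n) {
      X <- rbind(cbind(rnorm(n, -2), rnorm(n)), cbind(rnorm(n, 2), rnorm(n)))
      list(X = X, y = factor(rep(c("n", "p"), each = n)))
    }
    tr <- make(100); te <- make(100)
    mean(train_predict("lda", tr$X, tr$y, te$X) != te$y)
  })
  expect_lte(mean(errs), 0.05)          # Bayes error ~ 2.3%
})

test_that("pseudoquadratic discriminant handles singular covariances", {
  set.seed(5)
  X <- cbind(rnorm(40), rnorm(40))
  X <- cbind(X, X[, 1])                  # exactly collinear column
  y <- factor(rep(c("n", "p"), each = 20))
  X[y == "p", ] <- X[y == "p", ] + 3
  expect_silent(pred <- train_predict("lda", X, y, X))
  expect_gt(mean(pred == y), 0.9)
})

test_that("levenberg-marquardt networks fit separable data", {
  set.seed(6)
  Xtr <- rbind(matrix(rnorm(100, -1.5), 50, 2), matrix(rnorm(100, 1.5), 50, 2))
  ytr <- factor(rep(c("n", "p"), each = 50))
  for (net in c("patnet", "fitnet")) {
    pred <- suppressWarnings(train_predict(net, Xtr, ytr, Xtr))
    expect_gt(mean(pred == ytr), 0.95)
  }
  expect_error(train_predict("patnet", Xtr, factor(rep("n", 100)), Xtr),
               "single class")
})

test_that("metrics reproduce hand-computed values and formulae", {
  m <- metrics(c(tp = 8, fn = 2, tn = 9, fp = 1))
  expect_equal(m[["sen"]], 80)
  expect_equal(m[["spe"]], 90)
  expect_equal(m[["acc"]], 85)
  expect_equal(m[["precision"]], 100 * 8 / 9)

  perfect <- metrics(c(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_true(all(perfect == 100))

  all_pos <- metrics(c(tp = 10, fn = 0, tn = 0, fp = 10))
  expect_equal(all_pos[["sen"]], 100)
  expect_equal(all_pos[["spe"]], 0)
  expect_equal(all_pos[["acc"]], 50)

  expect_warning(z <- metrics(c(tp = 0, fn = 0, tn = 5, fp = 0)),
                 "sensitivity undefined")
  expect_true(is.na(z[["sen"]]))

  # property: random confusion tables match the direct formulas
  set.seed(7)
  for (i in 1:200) {
    counts <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
                tn = sample(0:30, 1), fn = sample(0:30, 1))
    if (sum(counts) == 0) next
    m <- suppressWarnings(metrics(counts))
    expect_equal(m[["acc"]], 100 * (counts[["tp"]] + counts[["tn"]]) / sum(counts))
    if (counts[["tp"]] + counts[["fn"]] > 0)
      expect_equal(m[["sen"]], 100 * counts[["tp"]] /
                                 (counts[["tp"]] + counts[["fn"]]))
    if (counts[["tn"]] + counts[["fp"]] > 0)
      expect_equal(m[["spe"]], 100 * counts[["tn"]] /
                                 (counts[["tn"]] + counts[["fp"]]))
  }
})

test_that("cross-validation tests each sample exactly once and is reproducible", {
  set.seed(8)
  X <- rbind(matrix(rnorm(80, -1), 40, 2), matrix(rnorm(80, 1), 40, 2))
  y <- factor(rep(c("benign", "malignant"), each = 40))
  plan <- make_folds(y, k = 10, seed = 2)
  rep1 <- cross_validate(X, y, plan, classifiers = c("knn", "lda"))
  expect_identical(sum(rep1$classifiers$knn$folds), 80L)
  rep2 <- cross_validate(X, y, plan, classifiers = c("knn", "lda"))
  expect_identical(rep1$classifiers$knn$folds, rep2$classifiers$knn$folds)
  expect_identical(rep1$positive, "malignant")
})

test_that("regime experiment nests texture inside combined and ranks them", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 7), n)
  colnames(X) <- c("contrast", "energy", "entropy", "fd", "kse", "lle", "cd")
  y <- factor(rep(c("benign", "malignant"), each = n / 2))
  X[y == "malignant", "fd"] <- X[y == "malignant", "fd"] + 2
  regs <- feature_regimes(colnames(X))
  expect_true(all(regs$texture_only %in% regs$combined))
  expect_true(all(regs$nonlinear_only %in% regs$combined))
  plan <- make_folds(y, k = 5, seed = 1)
  reps <- run_experiment(X, y, regs, plan, classifiers = "knn")
  acc <- attr(reps, "accuracy")
  expect_identical(dim(acc), c(3L, 1L))
  # fd carries the only signal: nonlinear and combined beat texture-only
  expect_gt(acc["nonlinear_only", 1], acc["texture_only", 1])
})

test_that("holdout evaluation returns counts that sum to the test split", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60, -1), 30, 2), matrix(rnorm(60, 1), 30, 2))
  y <- factor(rep(c("benign", "malignant"), each = 30))
  h <- evaluate_holdout(X, y, train_frac = 0.7, classifiers = "knn", seed = 4)
  expect_identical(sum(h$knn$counts), 18L)
})
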