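#' Cross-validation fold plan
#'
#' Deterministic (seeded) k-fold assignment. With `stratified = TRUE` the
#' class proportions of every fold match the data within one sample; fold
#' sizes differ by at most one.
#'
#' @param labels factor (or coercible) of class labels.
#' @param k folds, default 10.
#' @param seed integer seed.
#' @param stratified keep class ratios per fold.
#' @return a `fold_plan`: `k`, `assignments` (integer per sample), `seed`,
#'   `stratified`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  n <- length(labels)
  if (k > n) stopf("k = %d exceeds the number of samples (%d)", k, n)
  if (stratified && k > min(table(labels)))
    stopf("k exceeds the smallest class count; use stratified = FALSE")
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      pos <- 0L
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        assignments[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
        pos <- pos + length(idx)
      }
    } else {
      assignments <- sample(rep(seq_len(k), length.out = n))
    }
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_plan")
}

# column-wise standardisation by training-set statistics only
#' @noRd
standardize_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Train one classifier and predict test labels
#'
#' The five classifiers of the evaluation harness. Features are standardized
#' with training-fold statistics only (no test leakage).
#' \describe{
#'   \item{svm}{soft-margin machine with Gaussian RBF kernel
#'     `exp(-||u-v||^2 / (2 sigma^2))`, `sigma` = median pairwise training
#'     distance, cost 1 (via \pkg{e1071}).}
#'   \item{knn}{majority vote of the 5 nearest training samples.}
#'   \item{lda}{"pseudoquadratic" discriminant: per-class Gaussian with
#'     Moore-Penrose pseudo-inverted covariance, so singular covariances are
#'     handled.}
#'   \item{patnet}{pattern-recognition network: one hidden layer of 10 tanh
#'     units, one output unit per class trained on one-hot targets by
#'     Levenberg-Marquardt least squares; predicted class = argmax output.}
#'   \item{fitnet}{function-fitting network: same body, a single linear
#'     output trained toward 0/1 and thresholded at 0.5.}
#' }
#'
#' @param name one of `"svm"`, `"knn"`, `"lda"`, `"patnet"`, `"fitnet"`.
#' @param Xtr,ytr training features (matrix) and labels (factor).
#' @param Xte test features.
#' @param cfg optional list of overrides (`cost`, `sigma`, `knn_k`,
#'   `hidden`, `max_iter`, `seed`).
#' @return factor of predicted test labels (levels of `ytr`).
#' @export
train_predict <- function(name = c("svm", "knn", "lda", "patnet", "fitnet"),
                          Xtr, ytr, Xte, cfg = list()) {
  name <- match.arg(name)
  ytr <- as.factor(ytr)
  if (nlevels(droplevels(ytr)) < 2L) stopf("training data has a single class")
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  std <- standardize_train_test(Xtr, Xte)
  Xtr <- std$train; Xte <- std$test
  switch(name,
    knn = {
      class::knn(Xtr, Xte, ytr, k = cfg$knn_k %||% 5L, use.all = TRUE)
    },
    svm = {
      sigma <- cfg$sigma %||% stats::median(stats::dist(Xtr))
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
      fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                        gamma = 1 / (2 * sigma^2),
                        cost = cfg$cost %||% 1, scale = FALSE)
      stats::predict(fit, Xte)
    },
    lda = pseudoquadratic_predict(Xtr, ytr, Xte),
    patnet = {
      net <- lm_net_train(Xtr, one_hot(ytr), hidden = cfg$hidden %||% 10L,
                          max_iter = cfg$max_iter %||% 200L,
                          seed = cfg$seed %||% 1L)
      out <- lm_net_forward(net, Xte)
      factor(levels(ytr)[max.col(out, ties.method = "first")],
             levels = levels(ytr))
    },
    fitnet = {
      tgt <- matrix(as.numeric(ytr == levels(ytr)[2]), ncol = 1)
      net <- lm_net_train(Xtr, tgt, hidden = cfg$hidden %||% 10L,
                          max_iter = cfg$max_iter %||% 200L,
                          seed = cfg$seed %||% 1L)
      out <- lm_net_forward(net, Xte)
      factor(levels(ytr)[1L + (out[, 1] > 0.5)], levels = levels(ytr))
    })
}

#' @noRd
one_hot <- function(y) {
  y <- as.factor(y)
  out <- matrix(0, length(y), nlevels(y))
  out[cbind(seq_along(y), as.integer(y))] <- 1
  out
}

# quadratic discriminant with Moore-Penrose pseudo-inverted class covariances
#' @noRd
pseudoquadratic_predict <- function(Xtr, ytr, Xte) {
  classes <- levels(ytr)
  scores <- sapply(classes, function(cl) {
    Xc <- Xtr[ytr == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    S <- stats::cov(Xc) * (nrow(Xc) - 1) / nrow(Xc)   # ML covariance
    eg <- eigen(S, symmetric = TRUE)
    tol <- max(eg$values, 0) * 1e-10
    pos <- eg$values > tol
    if (!any(pos)) return(rep(log(nrow(Xc) / nrow(Xtr)), nrow(Xte)))
    V <- eg$vectors[, pos, drop = FALSE]
    Sinv <- V %*% (t(V) / eg$values[pos])
    logdet <- sum(log(eg$values[pos]))
    Xc0 <- sweep(Xte, 2, mu)
    -0.5 * rowSums((Xc0 %*% Sinv) * Xc0) - 0.5 * logdet +
      log(nrow(Xc) / nrow(Xtr))
  })
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}

# ---- Levenberg-Marquardt single-hidden-layer network ----------------------
# One hidden layer of tanh units, linear outputs, sum-squared error.
# Damped Gauss-Newton: solve (J'J + lambda I) delta = J'r and accept the
# step when the error decreases (lambda /= 10), otherwise raise lambda
# (x 10). Stops at max_iter, lambda overflow, or a negligible error change.
# Weight initialisation is seeded so training is reproducible.

# parameter layout: theta = c(vec(W1), vec(W2)),
# W1: hidden x (d+1) (bias first column), W2: o x (hidden+1)
#' @noRd
lm_net_train <- function(X, Y, hidden = 10L, max_iter = 200L, seed = 1L,
                         lambda0 = 1e-3, tol = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); d <- ncol(X); o <- ncol(Y)
  n1 <- hidden * (d + 1L)
  npar <- n1 + o * (hidden + 1L)
  theta <- with_seed(seed, stats::runif(npar, -0.5, 0.5))
  X1 <- cbind(1, X)
  unpack <- function(th) list(
    W1 = matrix(th[seq_len(n1)], hidden, d + 1L),
    W2 = matrix(th[n1 + seq_len(npar - n1)], o, hidden + 1L))
  forward <- function(w) {
    A <- tanh(X1 %*% t(w$W1))
    list(A = A, Yhat = cbind(1, A) %*% t(w$W2))
  }
  # J = d vec(Yhat) / d theta  (columns of Yhat stacked, output k in rows
  # (k-1)n + 1..kn, matching as.numeric(Y - Yhat))
  jac <- function(w, f) {
    J <- matrix(0, n * o, npar)
    dA <- 1 - f$A^2
    A1 <- cbind(1, f$A)
    for (k in seq_len(o)) {
      rows <- (k - 1L) * n + seq_len(n)
      for (h in seq_len(hidden)) {
        cols <- (seq_len(d + 1L) - 1L) * hidden + h       # vec(W1)[h, j]
        J[rows, cols] <- (w$W2[k, h + 1L] * dA[, h]) * X1
      }
      cols <- n1 + (seq_len(hidden + 1L) - 1L) * o + k    # vec(W2)[k, c]
      J[rows, cols] <- A1
    }
    J
  }
  w <- unpack(theta)
  f <- forward(w)
  r <- as.numeric(Y - f$Yhat)
  sse <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- jac(w, f)
    H <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    while (lambda <= 1e10) {
      delta <- tryCatch(solve(H + diag(lambda, npar), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        wc <- unpack(cand)
        fc <- forward(wc)
        rc <- as.numeric(Y - fc$Yhat)
        if (sum(rc^2) < sse) {
          theta <- cand; w <- wc; f <- fc
          improvement <- sse - sum(rc^2)
          r <- rc; sse <- sum(rc^2)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (improvement < tol * max(sse, 1e-12)) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("Levenberg-Marquardt reached max_iter; returning best-so-far weights")
  structure(list(W1 = w$W1, W2 = w$W2, sse = sse, hidden = hidden),
            class = "lm_net")
}

#' @noRd
lm_net_forward <- function(net, X) {
  A <- tanh(cbind(1, as.matrix(X)) %*% t(net$W1))
  cbind(1, A) %*% t(net$W2)
}

#' Confusion counts
#' @param pred,truth factors with identical levels.
#' @param positive the positive-class label (the malignant/sick class).
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, positive) {
  c(tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    tn = sum(pred != positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

#' Accuracy, sensitivity, specificity and precision from confusion counts
#'
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`, `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`, `precision = TP/(TP+FP)`, all in percent. A ratio
#' with a zero denominator is reported as `NA` with a warning (and excluded
#' from fold averages by the callers).
#'
#' @param counts vector with entries `tp`, `fp`, `tn`, `fn`.
#' @return named numeric vector `acc`, `sen`, `spe`, `precision` (percent).
#' @examples
#' metrics(c(tp = 8, fn = 2, tn = 9, fp = 1))
#' @export
metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- tp + fp + tn + fn
  if (total < 1) stopf("no tested samples")
  ratio <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator)", what); NA_real_ }
    else 100 * num / den
  }
  c(acc = 100 * (tp + tn) / total,
    sen = ratio(tp, tp + fn, "sensitivity"),
    spe = ratio(tn, tn + fp, "specificity"),
    precision = ratio(tp, tp + fp, "precision"))
}

#' Cross-validated evaluation of the classifier suite
#'
#' Runs every requested classifier over the folds of `plan`, collecting
#' fold-wise confusion counts, pooled metrics, and the per-fold
#' mean and standard deviation of each metric (folds with an undefined
#' metric are excluded from that average).
#'
#' @param X feature matrix (samples x features), raw scale; standardisation
#'   happens inside each training fold.
#' @param y factor of labels.
#' @param plan a [make_folds()] plan.
#' @param classifiers character vector of [train_predict()] names.
#' @param positive positive-class label; default the second factor level.
#' @param cfg per-classifier config overrides.
#' @return an `evaluation_report`: per classifier a list with `folds`
#'   (k x 4 count matrix), `pooled` metrics, `mean`, `sd`.
#' @export
cross_validate <- function(X, y,
                           plan = make_folds(y),
                           classifiers = c("svm", "knn", "lda", "patnet",
                                           "fitnet"),
                           positive = NULL, cfg = list()) {
  y <- as.factor(y)
  X <- as.matrix(X)
  positive <- positive %||% levels(y)[2]
  out <- list()
  for (cl in classifiers) {
    folds <- matrix(0L, plan$k, 4L,
                    dimnames = list(NULL, c("tp", "fp", "tn", "fn")))
    for (f in seq_len(plan$k)) {
      te <- plan$assignments == f
      pred <- train_predict(cl, X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE], cfg)
      folds[f, ] <- confusion_counts(pred, y[te], positive)
    }
    fold_metrics <- suppressWarnings(t(apply(folds, 1, metrics)))
    out[[cl]] <- list(
      folds = folds,
      pooled = metrics(colSums(folds)),
      mean = colMeans(fold_metrics, na.rm = TRUE),
      sd = apply(fold_metrics, 2, stats::sd, na.rm = TRUE))
  }
  structure(list(classifiers = out, positive = positive, plan = plan),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d-fold CV, positive class '%s'>\n",
              x$plan$k, x$positive))
  m <- t(vapply(x$classifiers, function(cl) cl$pooled, numeric(4)))
  print(round(m, 2))
  invisible(x)
}

#' Feature-regime comparison experiment
#'
#' Evaluates the classifier suite on texture-only, nonlinear-only and
#' combined feature columns under one common fold plan, the experiment that
#' shows whether joining the two feature families buys accuracy over either
#' alone.
#'
#' @param X full feature matrix with named columns.
#' @param y factor of labels.
#' @param regimes named list of column-name (or index) vectors; default the
#'   package's three standard regimes from [feature_regimes()].
#' @param plan a [make_folds()] plan.
#' @param classifiers classifier names.
#' @param positive positive-class label.
#' @param cfg per-classifier overrides.
#' @return named list of `evaluation_report`s, one per regime, with an
#'   `accuracy` attribute (regime x classifier pooled accuracy matrix).
#' @export
run_experiment <- function(X, y, regimes = feature_regimes(colnames(X)),
                           plan = make_folds(y),
                           classifiers = c("svm", "knn", "lda", "patnet",
                                           "fitnet"),
                           positive = NULL, cfg = list()) {
  X <- as.matrix(X)
  reports <- lapply(regimes, function(cols)
    cross_validate(X[, cols, drop = FALSE], y, plan, classifiers,
                   positive, cfg))
  acc <- do.call(rbind, lapply(reports, function(rep)
    vapply(rep$classifiers, function(cl) cl$pooled[["acc"]], numeric(1))))
  rownames(acc) <- names(regimes)
  attr(reports, "accuracy") <- acc
  reports
}

#' Standard feature regimes of the 25-column feature table
#'
#' @param feature_names column names of the feature table.
#' @return named list with `texture_only` (the 21 co-occurrence
#'   descriptors), `nonlinear_only` (fd, lle, kse, cd) and `combined`.
#' @export
feature_regimes <- function(feature_names) {
  nonlinear <- c("fd", "lle", "kse", "cd")
  if (!all(nonlinear %in% feature_names))
    stopf("feature table lacks the nonlinear columns fd, lle, kse, cd")
  texture <- setdiff(feature_names, nonlinear)
  list(texture_only = texture, nonlinear_only = nonlinear,
       combined = c(texture, nonlinear))
}

#' Single holdout split evaluation
#'
#' Optional alternative to cross-validation: a stratified
#' `train_frac`/`1 - train_frac` split evaluated once.
#'
#' @param X feature matrix; `y` labels.
#' @param y factor of labels.
#' @param train_frac training fraction, default 0.7.
#' @param classifiers classifier names.
#' @param positive positive-class label.
#' @param seed split seed.
#' @param cfg per-classifier overrides.
#' @return list of per-classifier confusion counts and metrics.
#' @export
evaluate_holdout <- function(X, y, train_frac = 0.7,
                             classifiers = c("svm", "knn", "lda", "patnet",
                                             "fitnet"),
                             positive = NULL, seed = 1L, cfg = list()) {
  y <- as.factor(y)
  X <- as.matrix(X)
  positive <- positive %||% levels(y)[2]
  tr <- with_seed(seed, {
    keep <- logical(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      keep[sample(idx, round(train_frac * length(idx)))] <- TRUE
    }
    keep
  })
  lapply(stats::setNames(classifiers, classifiers), function(cl) {
    pred <- train_predict(cl, X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], cfg)
    counts <- confusion_counts(pred, y[!tr], positive)
    list(counts = counts, metrics = suppressWarnings(metrics(counts)))
  })
}
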