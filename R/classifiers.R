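# Thin wrappers over the established classifier implementations
# (randomForest, e1071 SVM-RBF, MASS LDA, class kNN) with a shared
# fit/predict surface. Scale-sensitive learners (svm, lda, knn) are z-scored
# per column with training-fold statistics; the random forest consumes raw
# features.

.CLASSIFIERS <- c("rf", "svm", "lda", "knn")

# odd k below sqrt(n), per the usual kNN guidance
.knn_k <- function(n_train) {
  k <- floor(sqrt(n_train))
  if (k %% 2 == 0) k <- k - 1
  max(1L, as.integer(k))
}

.fit_classifier <- function(x, y, classifier, ...) {
  classifier <- match.arg(classifier, .CLASSIFIERS)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  scaled <- classifier %in% c("svm", "lda", "knn")
  ctr <- scl <- NULL
  keep <- seq_len(ncol(x))
  if (scaled) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    keep <- which(is.finite(scl) & scl > 0)
    if (!length(keep)) stop("all features are constant in the training fold")
    x <- scale(x[, keep, drop = FALSE], ctr[keep], scl[keep])
  }
  model <- switch(classifier,
    rf  = randomForest::randomForest(x = x, y = y, ...),
    svm = e1071::svm(x = x, y = y, kernel = "radial", scale = FALSE, ...),
    lda = MASS::lda(x, grouping = y),
    knn = list(train = x, y = y, k = .knn_k(nrow(x))))
  structure(list(classifier = classifier, model = model, levels = levels(y),
                 center = ctr, scale = scl, keep = keep),
            class = "bci_classifier")
}

.predict_classifier <- function(fit, newx) {
  newx <- as.matrix(newx)
  if (fit$classifier %in% c("svm", "lda", "knn"))
    newx <- scale(newx[, fit$keep, drop = FALSE],
                  fit$center[fit$keep], fit$scale[fit$keep])
  out <- switch(fit$classifier,
    rf  = predict(fit$model, newx),
    svm = predict(fit$model, newx),
    lda = predict(fit$model, newx)$class,
    knn = class::knn(fit$model$train, newx, fit$model$y, k = fit$model$k))
  factor(as.character(out), levels = fit$levels)
}

# Stratified train/test partition: within each stratum, round(n * split)
# rows train (clamped so both sides are non-empty when n >= 2).
.stratified_split <- function(strata, split) {
  train <- logical(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- round(length(idx) * split)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    if (length(idx) == 1L) n_tr <- 1L
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# per-repeat RNG seeds derived from one master seed
.repeat_seeds <- function(seed, repeats) {
  set.seed(seed)
  sample.int(.Machine$integer.max, repeats)
}
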