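#' SMOTE class balancing
#'
#' Synthetic minority oversampling: new minority samples are interpolated
#' at a uniform random position on the segment between a minority sample
#' and one of its `k` nearest minority-class neighbours, until both classes
#' are equal-sized. Deterministic for a fixed seed; an already balanced
#' set is returned unchanged.
#'
#' @param features numeric matrix or data frame, samples in rows.
#' @param labels factor/vector with exactly 2 classes; the minority class
#'   needs >= 2 samples.
#' @param k number of minority neighbours to draw from (capped at the
#'   minority size minus 1).
#' @param seed integer seed.
#' @return list with `features` (original rows first, then synthetic),
#'   `labels`, and `synthetic` (logical row flags).
#' @export
smote_balance <- function(features, labels, k = 5L, seed = 1L) {
  X <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("SMOTE expects exactly 2 classes")
  tab <- table(labels)
  if (tab[1] == tab[2])
    return(list(features = X, labels = labels,
                synthetic = rep(FALSE, nrow(X))))
  minority <- names(tab)[which.min(tab)]
  Xm <- X[labels == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  if (n_min < 2L) stop("minority class needs at least 2 samples")
  n_new <- max(tab) - n_min
  k <- min(k, n_min - 1L)
  d2 <- outer(rowSums(Xm^2), rowSums(Xm^2), `+`) - 2 * tcrossprod(Xm)
  diag(d2) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d2[i, ])[seq_len(k)]))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  synth <- matrix(NA_real_, n_new, ncol(X))
  for (j in seq_len(n_new)) {
    i <- ((j - 1L) %% n_min) + 1L
    nb <- nn[i, sample.int(k, 1L)]
    lam <- stats::runif(1)
    synth[j, ] <- Xm[i, ] + lam * (Xm[nb, ] - Xm[i, ])
  }
  colnames(synth) <- colnames(X)
  list(features = rbind(X, synth),
       labels = factor(c(as.character(labels), rep(minority, n_new)),
                       levels = levels(labels)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}

#' Leave-one-out cross-validated random-forest classification
#'
#' For each held-out case, SMOTE balancing is applied to the training fold
#' only (no leakage into the held-out case), a random forest with
#' `ntree` trees and default parameters (`mtry = sqrt(p)`, unlimited
#' depth) is trained, and the held-out vote fraction for the positive class
#' is recorded. Reports the AUC of the out-of-fold scores with a
#' stratified-bootstrap 95% CI, the confusion rates at the majority-vote
#' threshold, and Gini importances averaged over folds.
#'
#' @param features numeric matrix/data frame of predictors, samples in
#'   rows.
#' @param labels 2-class factor; >= 2 cases per class.
#' @param positive positive-class label (default: the second factor
#'   level).
#' @param ntree number of trees.
#' @param seed integer seed (folds derive their own seeds from it).
#' @param threshold vote threshold for the confusion rates.
#' @param boot bootstrap replicates for the AUC CI.
#' @return object of class `cv_result`: `auc`, `auc_ci`, `tpr`, `tnr`,
#'   `fpr`, `fnr`, `scores` (per-case out-of-fold scores), `labels`,
#'   `importance` (mean Gini decrease per feature).
#' @export
loocv_rf <- function(features, labels, positive = NULL, ntree = 100L,
                     seed = 1L, threshold = 0.5, boot = 2000L) {
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly 2 classes")
  if (any(table(labels) < 2L)) stop("need >= 2 cases per class")
  if (is.null(positive)) positive <- levels(labels)[2]
  n <- nrow(X)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  scores <- numeric(n)
  imp <- matrix(0, ncol(X), n, dimnames = list(colnames(X), NULL))
  for (i in seq_len(n)) {
    bal <- smote_balance(X[-i, , drop = FALSE], labels[-i],
                         seed = seed + 17L * i)
    set.seed((seed + 31L * i) %% .Machine$integer.max)
    rf <- randomForest::randomForest(bal$features, bal$labels,
                                     ntree = ntree)
    scores[i] <- stats::predict(rf, X[i, , drop = FALSE],
                                type = "prob")[, positive]
    imp[, i] <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  }

  is_pos <- labels == positive
  pred_pos <- scores > threshold
  tpr <- sum(pred_pos & is_pos) / sum(is_pos)
  tnr <- sum(!pred_pos & !is_pos) / sum(!is_pos)

  roc <- pROC::roc(response = is_pos, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  auc <- as.numeric(pROC::auc(roc))

  set.seed((seed + 997L) %% .Machine$integer.max)
  pos_idx <- which(is_pos)
  neg_idx <- which(!is_pos)
  boot_auc <- vapply(seq_len(boot), function(b) {
    bi <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
            sample(neg_idx, length(neg_idx), replace = TRUE))
    r <- pROC::roc(response = is_pos[bi], predictor = scores[bi],
                   quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))
    as.numeric(pROC::auc(r))
  }, numeric(1))
  ci <- stats::quantile(boot_auc, c(0.025, 0.975), names = FALSE)

  structure(list(auc = auc, auc_ci = ci, tpr = tpr, tnr = tnr,
                 fpr = 1 - tnr, fnr = 1 - tpr, scores = scores,
                 labels = labels, positive = positive,
                 importance = rowMeans(imp)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV random forest: AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  TPR %.2f TNR %.2f FPR %.2f FNR %.2f (positive: %s)\n",
              x$tpr, x$tnr, x$fpr, x$fnr, x$positive))
  invisible(x)
}

#' Rank features by Gini importance
#'
#' @param result a [loocv_rf()] result.
#' @param k how many top features to return.
#' @return character vector of feature names, descending mean Gini
#'   importance, ties broken alphabetically.
#' @export
rank_features <- function(result, k = 5L) {
  stopifnot(inherits(result, "cv_result"))
  imp <- result$importance
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(min(k, length(imp)))]
}
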