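#' Two-by-two confusion matrix
#'
#' @param y_true,y_pred Equal-length binary label vectors (at most two
#'   distinct values across both).
#' @param positive_label The value counted as positive.
#' @return Object of class `confusion_matrix`: list with integer `tp`,
#'   `fn`, `fp`, `tn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), positive_label = 1)
#' @export
confusion <- function(y_true, y_pred, positive_label = 1) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2L) {
    stop("more than two classes: ", paste(labs, collapse = ", "))
  }
  pos_t <- y_true == positive_label
  pos_p <- y_pred == positive_label
  structure(list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 fp = sum(!pos_t & pos_p), tn = sum(!pos_t & !pos_p)),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param tp,fn,fp,tn Non-negative counts, for building a matrix
#'   directly from published tallies.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity and specificity as percentages; true-positive
#' and false-positive rates as fractions:
#' accuracy = (TP+TN)/(TP+TN+FP+FN) x 100,
#' sensitivity = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100,
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN). A metric whose denominator is
#' zero is `NA` and listed in `undefined` rather than reported as 0.
#'
#' @param cm A [confusion_matrix].
#' @return Object of class `metric_set`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percent), `tpr`, `fpr` (fractions),
#'   `undefined` (character vector).
#' @examples
#' metrics(confusion_matrix(tp = 26, fn = 2, fp = 2, tn = 117))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix")
  pos <- cm$tp + cm$fn
  neg <- cm$fp + cm$tn
  sens <- if (pos > 0) cm$tp / pos * 100 else NA_real_
  spec <- if (neg > 0) cm$tn / neg * 100 else NA_real_
  undefined <- c(if (pos == 0) c("sensitivity", "tpr"),
                 if (neg == 0) c("specificity", "fpr"))
  structure(list(accuracy = (cm$tp + cm$tn) / total * 100,
                 sensitivity = sens,
                 specificity = spec,
                 tpr = if (pos > 0) cm$tp / pos else NA_real_,
                 fpr = if (neg > 0) cm$fp / neg else NA_real_,
                 undefined = undefined %||% character(0)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy    %6.2f %%\n", x$accuracy))
  cat(sprintf("sensitivity %6.2f %%\n", x$sensitivity))
  cat(sprintf("specificity %6.2f %%\n", x$specificity))
  cat(sprintf("TPR          %5.2f\n", x$tpr))
  cat(sprintf("FPR          %5.3f\n", x$fpr))
  if (length(x$undefined)) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct scores (ties stepped
#' simultaneously), collecting (FPR, TPR) points from (0,0) to (1,1),
#' and integrates by the trapezoidal rule. Equivalent to the
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs
#' ranked correctly, counting ties one half.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param y_true Labels, same length.
#' @param positive_label The value counted as positive.
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   of fpr, tpr, ordered) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, y_true, positive_label = 1) {
  if (length(scores) != length(y_true)) stop("length mismatch")
  pos <- y_true == positive_label
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # step simultaneously over tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Seeded random train/test split
#'
#' The training set holds round-half-up(fraction x N) ids after a seeded
#' shuffle; simple random (unstratified) division by default, matching
#' the usual random-division protocol, with an optional stratified mode.
#'
#' @param ids Vector of object ids (length >= 2).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @param stratify Optional vector of class labels aligned with `ids`;
#'   when given, the split is drawn within each class.
#' @return List with `train` and `test` id vectors.
#' @examples
#' sp <- split_ids(1:147, 0.8, seed = 42)
#' length(sp$train)  # 118
#' @export
split_ids <- function(ids, train_fraction = 0.8, seed = 1L,
                      stratify = NULL) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 objects to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (is.null(stratify)) {
    n_train <- round_half_up(train_fraction * n)
    perm <- with_seed(seed, sample(ids))
    list(train = perm[seq_len(n_train)], test = perm[-seq_len(n_train)])
  } else {
    stopifnot(length(stratify) == n)
    parts <- with_seed(seed, {
      lapply(split(ids, stratify), function(grp) {
        k <- round_half_up(train_fraction * length(grp))
        perm <- sample(grp)
        list(train = perm[seq_len(k)], test = perm[-seq_len(k)])
      })
    })
    list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
         test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  }
}

#' Seeded k-fold partition
#'
#' Shuffles the ids once under the seed and deals them into k disjoint
#' covering folds of size floor(N/k) or floor(N/k)+1.
#'
#' @param ids Vector of object ids (length >= k).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of k id vectors.
#' @export
kfold_ids <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("fewer objects than folds")
  perm <- with_seed(seed, sample(ids))
  unname(split(perm, rep(seq_len(k), length.out = n)))
}

#' Cross-validated accuracy of the network on a feature matrix
#'
#' Runs k-fold cross-validation: for each fold, trains on the remaining
#' folds and scores the held-out fold. Used to validate the training
#' portion before the final held-out test evaluation.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param config A [bpnn_config()].
#' @param k Folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `fold_accuracy` (percent, one per fold) and `mean_accuracy`.
#' @export
cv_bpnn <- function(X, y, config = bpnn_config(), k = 10L, seed = 1L) {
  X <- as.matrix(X)
  folds <- kfold_ids(seq_len(nrow(X)), k = k, seed = seed)
  acc <- vapply(folds, function(test_idx) {
    fit <- train_bpnn(X[-test_idx, , drop = FALSE], y[-test_idx], config)
    pred <- predict(fit, X[test_idx, , drop = FALSE])
    mean(pred$labels == y[test_idx]) * 100
  }, numeric(1))
  list(fold_accuracy = unname(acc), mean_accuracy = mean(acc))
}
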