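# Model evaluation: confusion matrix, per-class accuracy/sensitivity/
# specificity, one-versus-rest ROC/AUC, stratified k-fold cross-validation,
# and traceable-diagram records.

#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in 1..K (`NA` predictions are
#'   counted in a separate `none` column).
#' @param n_classes K (default 6).
#' @return A K x K (or K x (K+1)) matrix of counts, rows = true labels,
#'   columns = predicted, class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 6) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  lv <- seq_len(n_classes)
  has_na <- anyNA(y_pred)
  pred <- factor(ifelse(is.na(y_pred), "none", y_pred),
                 levels = c(lv, if (has_na) "none"))
  cm <- table(true = factor(y_true, levels = lv), predicted = pred)
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

# one-vs-rest counts for one class
.ovr_counts <- function(cm, class_id) {
  k <- as.character(class_id)
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class accuracy, sensitivity and specificity
#'
#' One-versus-rest counts from the confusion matrix and the ratios
#' `ACC = (TP + TN) / (TP + FN + FP + TN)`,
#' `TPR = TP / (TP + FN)` (sensitivity),
#' `FPR = FP / (FP + TN)` (= 1 - specificity).
#' A 0/0 ratio is reported as `NA`.
#'
#' @param cm a [confusion()] matrix.
#' @param class_id positive class (1..K).
#' @return Named numeric: `TP, FN, FP, TN, ACC, TPR, FPR, specificity`.
#' @export
metrics <- function(cm, class_id) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ct <- .ovr_counts(cm, class_id)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- rat(ct["TP"] + ct["TN"], sum(ct))
  tpr <- rat(ct["TP"], ct["TP"] + ct["FN"])
  fpr <- rat(ct["FP"], ct["FP"] + ct["TN"])
  c(ct, ACC = unname(acc), TPR = unname(tpr), FPR = unname(fpr),
    specificity = unname(if (is.na(fpr)) NA_real_ else 1 - fpr))
}

#' One-versus-rest ROC curve and AUC
#'
#' Sweeps a threshold over the positive-class score: each unique score
#' value yields one (FPR, TPR) operating point; the AUC is the trapezoidal
#' area under the resulting curve. For ANFIS crisp outputs use
#' [anfis_class_scores()] to obtain per-class scores first.
#'
#' @param scores numeric vector of positive-class scores (one per segment),
#'   or a matrix of per-class scores whose column `positive_class` is used.
#' @param y_true integer labels.
#' @param positive_class the class treated as positive.
#' @return An object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `positive_class`.
#' @export
ovr_roc <- function(scores, y_true, positive_class) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)[, as.character(positive_class)]
  }
  stopifnot(length(scores) == length(y_true), all(is.finite(scores)))
  pos <- y_true == positive_class
  if (all(pos) || !any(pos)) {
    stop("ROC needs both positive and negative examples", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  tp <- cumsum(p)
  fp <- cumsum(!p)
  # one operating point per distinct score (threshold = that score)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc, positive_class = positive_class),
            class = "roc_curve")
}

#' Per-class scores from ANFIS crisp outputs
#'
#' The crisp output is a single ordinal estimate; the one-versus-rest score
#' for class k is the negative absolute distance `-|crisp - k|`. `NA`
#' crisps (out of inferring range) score `-Inf` replaced by the worst
#' finite distance minus 1.
#'
#' @param crisp numeric crisp outputs.
#' @param n_classes K (default 6).
#' @return n x K matrix of scores, columns named 1..K.
#' @export
anfis_class_scores <- function(crisp, n_classes = 6) {
  sc <- vapply(seq_len(n_classes), function(k) -abs(crisp - k),
               numeric(length(crisp)))
  worst <- if (all(is.na(sc))) -1 else min(sc, na.rm = TRUE) - 1
  sc[is.na(sc)] <- worst
  colnames(sc) <- seq_len(n_classes)
  sc
}

#' Stratified k-fold cross-validation
#'
#' Splits each class's segments evenly over k folds (shuffled under the
#' given seed), trains on k-1 folds and scores accuracy on the held-out
#' fold.
#'
#' @param X feature matrix or data.frame (raw scale; an `ex_id` column is
#'   ignored).
#' @param y integer labels 1..6; every class must have at least k members.
#' @param k folds (default 5).
#' @param model `"svm"` or `"anfis"`.
#' @param config model configuration ([svm_config()] or [anfis_config()]).
#' @param seed RNG seed for the fold shuffle.
#' @return An object of class `cv_result`: list with `k`, `fold_accuracy`,
#'   `mean_accuracy`, `folds` (fold id per row), `predictions`.
#' @export
kfold_cv <- function(X, y, k = 5, model = c("svm", "anfis"),
                     config = NULL, seed = 1L) {
  model <- match.arg(model)
  X <- .as_feature_matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), k >= 2)
  tab <- table(y)
  if (any(tab < k)) {
    stop("every class needs at least k members for k-fold CV", call. = FALSE)
  }
  if (is.null(config)) {
    config <- if (model == "svm") svm_config() else anfis_config()
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  preds <- integer(length(y))
  preds[] <- NA_integer_
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (model == "svm") {
      fit <- train_svm(X[tr, , drop = FALSE], y[tr], config)
      p <- predict_svm(fit, X[te, , drop = FALSE])$label
    } else {
      fit <- fit_anfis(X[tr, , drop = FALSE], y[tr], config)
      crisp <- suppressWarnings(predict_anfis(fit, X[te, , drop = FALSE]))
      p <- rep(NA_integer_, sum(te))
      ok <- is.finite(crisp)
      p[ok] <- crisp_to_label(crisp[ok])
    }
    preds[te] <- p
    acc[f] <- mean(!is.na(p) & p == y[te])
  }
  structure(list(k = k, fold_accuracy = acc, mean_accuracy = mean(acc),
                 folds = folds, predictions = preds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean accuracy %.4f (folds: %s)\n",
              x$k, x$mean_accuracy,
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Traceable-diagram records
#'
#' One record per evaluated segment: the true label, the model output
#' (integer label for the SVM, numeric crisp value for the ANFIS), the
#' label band `[k - 0.5, k + 0.4]` of the true label, and an outlier flag —
#' a segment is an outlier when the SVM prediction differs from the true
#' label, or when the ANFIS crisp value falls outside the true label's
#' band.
#'
#' @param y_true integer labels.
#' @param outputs integer predictions (`mode = "svm"`) or numeric crisp
#'   values (`mode = "anfis"`; `NA` = out of inferring range, flagged as
#'   outlier).
#' @param mode `"svm"` or `"anfis"`.
#' @return data.frame `segment, true, output, lower, upper, outlier`.
#' @export
trace_records <- function(y_true, outputs, mode = c("svm", "anfis")) {
  mode <- match.arg(mode)
  stopifnot(length(y_true) == length(outputs))
  lower <- y_true - 0.5
  upper <- y_true + 0.4
  outlier <- if (mode == "svm") {
    is.na(outputs) | outputs != y_true
  } else {
    is.na(outputs) | outputs < lower | outputs > upper
  }
  data.frame(segment = seq_along(y_true), true = y_true,
             output = outputs, lower = lower, upper = upper,
             outlier = outlier)
}

#' Full evaluation report
#'
#' Confusion matrix, per-class metrics and OVR ROC/AUC for a set of
#' predictions with per-class scores.
#'
#' @param y_true integer labels.
#' @param y_pred integer predictions.
#' @param scores n x K matrix of per-class scores (SVM posteriors or
#'   [anfis_class_scores()]), or `NULL` to skip the ROC block.
#' @param n_classes K (default 6).
#' @return An object of class `eval_report`: list with `cm`, `per_class`
#'   (data.frame), `roc` (list of `roc_curve` or `NULL`), `accuracy`.
#' @export
eval_report <- function(y_true, y_pred, scores = NULL, n_classes = 6) {
  cm <- confusion(y_true, y_pred, n_classes)
  per_class <- as.data.frame(t(vapply(seq_len(n_classes),
                                      function(k) metrics(cm, k),
                                      numeric(8))))
  per_class$class <- seq_len(n_classes)
  roc <- NULL
  if (!is.null(scores)) {
    roc <- lapply(seq_len(n_classes), function(k) {
      if (all(y_true == k) || !any(y_true == k)) return(NULL)
      ovr_roc(scores, y_true, k)
    })
  }
  structure(list(cm = cm, per_class = per_class, roc = roc,
                 accuracy = mean(!is.na(y_pred) & y_pred == y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  print(unclass(x$cm))
  if (!is.null(x$roc)) {
    aucs <- vapply(x$roc, function(r) if (is.null(r)) NA_real_ else r$auc, 0)
    cat("OVR AUC:", paste(sprintf("%.3f", aucs), collapse = " "), "\n")
  }
  invisible(x)
}
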