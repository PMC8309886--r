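# Multiclass SVM recognizer.
#
# One-versus-one reduction over binary polynomial-kernel SVMs: K classes
# yield K(K-1)/2 binary learners whose sigmoid-calibrated decision values
# are combined by pairwise coupling into per-class posterior scores; the
# predicted label is the argmax. Backed by libsvm via e1071.

#' SVM configuration
#'
#' Defaults follow the recognizer settings used for the six-exercise task:
#' third-order polynomial kernel, kernel scale 1, box constraint
#' (regularization) 1, one-versus-one coding.
#'
#' @param polynomial_order polynomial kernel degree (default 3).
#' @param kernel_scale kernel scale; the kernel is
#'   `((x . y) / kernel_scale^2 + 1)^order`.
#' @param box_constraint soft-margin cost C (default 1).
#' @param standardize z-score features before kernel evaluation (default
#'   `TRUE`; with kernel scale 1 the features must share a common scale).
#' @param outlier_fraction expected fraction of outliers in the training
#'   data, in \[0, 0.001\]; 0 disables it.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(polynomial_order = 3, kernel_scale = 1,
                       box_constraint = 1, standardize = TRUE,
                       outlier_fraction = 0) {
  stopifnot(polynomial_order >= 1, kernel_scale > 0, box_constraint > 0,
            outlier_fraction >= 0, outlier_fraction <= 0.001)
  structure(list(polynomial_order = polynomial_order,
                 kernel_scale = kernel_scale,
                 box_constraint = box_constraint,
                 standardize = standardize,
                 outlier_fraction = outlier_fraction),
            class = "svm_config")
}

#' Train the one-versus-one polynomial-kernel SVM
#'
#' @param X numeric feature matrix (rows = segments) or data.frame of
#'   feature columns (an `ex_id` column, if present, is ignored).
#' @param y integer class labels 1..6 (at least two classes present).
#' @param config an [svm_config()].
#' @return An object of class `svm_model` wrapping the fitted binary
#'   learners; `model$n_binary_learners` is K(K-1)/2.
#' @export
train_svm <- function(X, y, config = svm_config()) {
  X <- .as_feature_matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  # probability calibration in libsvm uses internal cross-validation;
  # fix the RNG substream so refitting the same data is reproducible
  seed_keep <- .save_rng()
  on.exit(.restore_rng(seed_keep))
  set.seed(20210714L)
  fit <- e1071::svm(
    x = X, y = factor(y, levels = classes),
    type = "C-classification", kernel = "polynomial",
    degree = config$polynomial_order,
    gamma = 1 / config$kernel_scale^2,
    coef0 = 1,
    cost = config$box_constraint,
    scale = config$standardize,
    probability = TRUE
  )
  k <- length(classes)
  structure(list(fit = fit, classes = classes,
                 n_binary_learners = (k * (k - 1L)) %/% 2L,
                 feature_names = colnames(X), config = config),
            class = "svm_model")
}

#' Predict with posterior-style class scores
#'
#' @param model an `svm_model`.
#' @param x a feature vector, matrix or data.frame matching the training
#'   columns.
#' @return A list with `label` (integer vector, argmax of the coupled
#'   scores, ties to the smallest label) and `posterior` (matrix, one row
#'   per input, columns named by class; rows sum to 1).
#' @export
predict_svm <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  x <- .as_feature_matrix(x, expected = model$feature_names)
  pr <- predict(model$fit, x, probability = TRUE)
  post <- attr(pr, "probabilities")
  post <- post[, as.character(model$classes), drop = FALSE]
  post <- post / rowSums(post)
  label <- model$classes[apply(post, 1, which.max)]
  list(label = as.integer(label), posterior = post)
}

#' Decode a posterior score vector to a class label
#'
#' The predicted class is the one whose posterior score approaches 1, i.e.
#' the argmax; ties are broken toward the smallest label index.
#'
#' @param posterior numeric vector of per-class scores (class k at
#'   position k).
#' @return Integer label.
#' @examples
#' decode_posterior(c(0.02, 0.01, 0.03, 0.05, 0.04, 0.98))  # 6
#' @export
decode_posterior <- function(posterior) {
  stopifnot(is.numeric(posterior), length(posterior) >= 2,
            all(is.finite(posterior)))
  which.max(posterior)
}

.as_feature_matrix <- function(X, expected = NULL) {
  if (is.data.frame(X)) {
    X <- X[, setdiff(names(X), "ex_id"), drop = FALSE]
    X <- as.matrix(X)
  } else if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  }
  storage.mode(X) <- "double"
  if (!is.null(expected)) {
    if (!is.null(colnames(X)) && all(expected %in% colnames(X))) {
      X <- X[, expected, drop = FALSE]
    } else if (ncol(X) != length(expected)) {
      stop("feature dimension mismatch: model expects ",
           length(expected), " features", call. = FALSE)
    } else {
      colnames(X) <- expected
    }
  }
  X
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}
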