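# Sugeno-type ANFIS recognizer.
#
# The fuzzy inference system is initialized by subtractive clustering: each
# cluster center found in the (normalized) joint input(+output) space seeds
# one rule with a Gaussian membership function per input. Hybrid training
# alternates a least-squares solve for the rule consequents with a
# normalized-gradient step on the membership centers and widths against the
# training RMSE. Inference is weighted-average defuzzification of the rule
# consequents; the crisp output is rounded to the nearest exercise label.

#' ANFIS configuration
#'
#' @param influence_range cluster influence range r_a as a fraction of the
#'   normalized (unit) data range (default 0.8).
#' @param squash_factor r_b = squash_factor * r_a (default 1.25), the
#'   neighbourhood squashed after each center is selected.
#' @param accept_ratio density ratio above which a candidate center is
#'   always accepted (default 0.5).
#' @param reject_ratio density ratio below which selection stops
#'   (default 0.15).
#' @param epochs hybrid training epochs (default 30).
#' @param step_size initial normalized-gradient step (default 0.01),
#'   multiplied by `step_increase` after an improving epoch and by
#'   `step_decrease` after a worsening one.
#' @param step_increase,step_decrease step-size adaptation factors.
#' @param include_output cluster on the joint input + output space
#'   (default `TRUE`; yields class-aware rules).
#' @param consequent `"constant"` (zero-order Sugeno, default) or
#'   `"linear"` (first-order).
#' @return A list of class `anfis_config`.
#' @export
anfis_config <- function(influence_range = 0.8, squash_factor = 1.25,
                         accept_ratio = 0.5, reject_ratio = 0.15,
                         epochs = 30, step_size = 0.01,
                         step_increase = 1.1, step_decrease = 0.9,
                         include_output = TRUE,
                         consequent = c("constant", "linear")) {
  stopifnot(influence_range > 0, squash_factor >= 1,
            reject_ratio > 0, reject_ratio < accept_ratio, accept_ratio <= 1,
            epochs >= 0, step_size > 0)
  structure(list(influence_range = influence_range,
                 squash_factor = squash_factor,
                 accept_ratio = accept_ratio, reject_ratio = reject_ratio,
                 epochs = epochs, step_size = step_size,
                 step_increase = step_increase, step_decrease = step_decrease,
                 include_output = include_output,
                 consequent = match.arg(consequent)),
            class = "anfis_config")
}

#' Subtractive clustering
#'
#' Density-based center selection on data normalized to the unit hypercube.
#' Each point's density is `D_i = sum_j exp(-||x_i - x_j||^2 / (r_a/2)^2)`;
#' the densest point becomes a center and its neighbourhood's density is
#' subtracted with radius `r_b = squash * r_a`. Selection continues while
#' the density ratio to the first center exceeds `accept_ratio`, stops below
#' `reject_ratio`, and in between accepts a candidate only if
#' `d_min/r_a + ratio >= 1` (`d_min` = distance to the nearest accepted
#' center), otherwise discards it and tries the next.
#'
#' @param X numeric matrix (rows = points) normalized to \[0, 1\] per
#'   column.
#' @param config an [anfis_config()].
#' @return Matrix of cluster centers (rows), at least one; attribute
#'   `density` carries the selection densities.
#' @export
subtractive_cluster <- function(X, config = anfis_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stop("empty data", call. = FALSE)
  r_a <- config$influence_range
  r_b <- config$squash_factor * r_a
  alpha <- 4 / r_a^2       # 1 / (r_a/2)^2
  beta <- 4 / r_b^2
  d2 <- as.matrix(stats::dist(X))^2
  D <- rowSums(exp(-alpha * d2))
  centers <- integer(0)
  dens <- numeric(0)
  D1 <- NULL
  Dw <- D
  for (iter in seq_len(n)) {
    i <- which.max(Dw)
    if (is.null(D1)) {
      D1 <- Dw[i]
      centers <- i
      dens <- Dw[i]
      Dw <- Dw - Dw[i] * exp(-beta * d2[, i])
      next
    }
    ratio <- Dw[i] / D1
    if (ratio < config$reject_ratio || Dw[i] <= 0) break
    if (ratio <= config$accept_ratio) {
      d_min <- sqrt(min(d2[i, centers]))
      if (d_min / r_a + ratio < 1) {
        Dw[i] <- 0
        next
      }
    }
    centers <- c(centers, i)
    dens <- c(dens, Dw[i])
    Dw <- Dw - Dw[i] * exp(-beta * d2[, i])
  }
  structure(X[centers, , drop = FALSE], density = dens)
}

# rule firing strengths: n x R matrix of Gaussian products
.fis_weights <- function(fis, Xn) {
  n <- nrow(Xn)
  R <- nrow(fis$centers)
  W <- matrix(0, n, R)
  for (r in seq_len(R)) {
    z <- sweep(Xn, 2, fis$centers[r, ], "-")
    z <- sweep(z, 2, fis$sigma[r, ], "/")
    W[, r] <- exp(-0.5 * rowSums(z^2))
  }
  W
}

# per-sample, per-rule consequent outputs (n x R)
.rule_outputs <- function(fis, Xn) {
  R <- nrow(fis$centers)
  if (fis$consequent == "constant") {
    matrix(fis$coef, nrow(Xn), R, byrow = TRUE)
  } else {
    cbind(Xn, 1) %*% t(fis$coef)   # coef: R x (m+1)
  }
}

# least-squares consequents given firing strengths
.solve_consequents <- function(fis, Xn, y, W) {
  S <- pmax(rowSums(W), .Machine$double.eps)
  Wb <- W / S
  if (fis$consequent == "constant") {
    A <- Wb
  } else {
    m <- ncol(Xn)
    A <- do.call(cbind, lapply(seq_len(ncol(W)), function(r) Wb[, r] * cbind(Xn, 1)))
  }
  # ridge-stabilized normal equations: near-duplicate rules can make A
  # rank deficient
  AtA <- crossprod(A) + diag(1e-8, ncol(A))
  coef <- solve(AtA, crossprod(A, y))
  if (fis$consequent == "constant") {
    fis$coef <- as.numeric(coef)
  } else {
    fis$coef <- matrix(coef, nrow = ncol(W), byrow = TRUE)
  }
  fis
}

#' Initialize a Sugeno FIS from cluster centers
#'
#' One rule per center: the rule's Gaussian membership on input j is
#' centered at the center's j-th coordinate with width
#' `sigma = r_a * range_j / sqrt(8)` (unit range after normalization).
#' Consequents are initialized by least squares on the training data.
#'
#' @param centers matrix from [subtractive_cluster()]; if clustering
#'   included the output column, its last column is dropped for the rules.
#' @param X normalized training inputs (n x m).
#' @param y numeric training targets (exercise ids).
#' @param config an [anfis_config()].
#' @return An object of class `fis`: list with `centers` (R x m), `sigma`
#'   (R x m), `coef` (consequents), `consequent`, and `norm` (set by
#'   [fit_anfis()]).
#' @export
init_fis <- function(centers, X, y, config = anfis_config()) {
  X <- as.matrix(X)
  m <- ncol(X)
  centers <- as.matrix(centers)
  if (ncol(centers) == m + 1) centers <- centers[, seq_len(m), drop = FALSE]
  stopifnot(ncol(centers) == m, nrow(centers) >= 1)
  sigma <- matrix(config$influence_range / sqrt(8), nrow(centers), m)
  fis <- structure(
    list(centers = centers, sigma = sigma,
         coef = NULL, consequent = config$consequent,
         norm = NULL, config = config),
    class = "fis"
  )
  W <- .fis_weights(fis, X)
  .solve_consequents(fis, X, y, W)
}

.fis_eval <- function(fis, Xn, min_weight = 1e-12) {
  W <- .fis_weights(fis, Xn)
  S <- rowSums(W)
  L <- .rule_outputs(fis, Xn)
  out <- rowSums(W * L) / pmax(S, .Machine$double.eps)
  out[S < min_weight] <- NA_real_
  out
}

#' Hybrid training of an ANFIS
#'
#' Per epoch: (1) least-squares solve for the consequents given the current
#' memberships, (2) one normalized-gradient step on all membership centers
#' and widths against the training mean squared error, with adaptive step
#' size. The state with the lowest RMSE seen is returned.
#'
#' @param fis an initialized [init_fis()] (inputs must be on the same
#'   normalized scale as `X`).
#' @param X normalized training inputs.
#' @param y numeric targets.
#' @param epochs number of epochs (0 returns the FIS unchanged).
#' @param config an [anfis_config()] (step-size settings).
#' @return A list with `fis` (best state) and `report` (class
#'   `anfis_report`: `rmse` per epoch, `final_rmse`).
#' @export
train_anfis <- function(fis, X, y, epochs = fis$config$epochs,
                        config = fis$config) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  rmse_hist <- numeric(0)
  if (epochs == 0) {
    return(list(fis = fis,
                report = structure(list(rmse = numeric(0),
                                        final_rmse = NA_real_),
                                   class = "anfis_report")))
  }
  eta <- config$step_size
  best <- fis
  best_rmse <- Inf
  prev_rmse <- Inf
  for (ep in seq_len(epochs)) {
    W <- .fis_weights(fis, X)
    fis <- .solve_consequents(fis, X, y, W)
    S <- pmax(rowSums(W), .Machine$double.eps)
    L <- .rule_outputs(fis, X)
    yhat <- rowSums(W * L) / S
    e <- yhat - y
    rmse <- sqrt(mean(e^2))
    if (!is.finite(rmse)) {
      stop("ANFIS training diverged (non-finite RMSE) at epoch ", ep,
           call. = FALSE)
    }
    rmse_hist <- c(rmse_hist, rmse)
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- fis
    }
    eta <- eta * if (rmse < prev_rmse) config$step_increase else config$step_decrease
    prev_rmse <- rmse

    # gradient of the MSE wrt membership centers and widths
    n <- length(y)
    common <- (2 / n) * e * (1 / S)          # n
    gc_ <- fis$centers * 0
    gs_ <- fis$sigma * 0
    for (r in seq_len(nrow(fis$centers))) {
      dr <- common * (L[, r] - yhat) * W[, r]  # n
      Z <- sweep(X, 2, fis$centers[r, ], "-")
      gc_[r, ] <- colSums(dr * sweep(Z, 2, fis$sigma[r, ]^2, "/"))
      gs_[r, ] <- colSums(dr * sweep(Z^2, 2, fis$sigma[r, ]^3, "/"))
    }
    gnorm <- sqrt(sum(gc_^2) + sum(gs_^2))
    if (gnorm > 0) {
      fis$centers <- fis$centers - eta * gc_ / gnorm
      fis$sigma <- pmax(fis$sigma - eta * gs_ / gnorm, 1e-3)
    }
  }
  # final consequent solve for the best membership state
  W <- .fis_weights(best, X)
  best <- .solve_consequents(best, X, y, W)
  yhat <- .fis_eval(best, X)
  final_rmse <- sqrt(mean((yhat - y)^2))
  if (is.finite(final_rmse) && final_rmse < best_rmse) best_rmse <- final_rmse
  list(fis = best,
       report = structure(list(rmse = rmse_hist, final_rmse = best_rmse),
                          class = "anfis_report"))
}

#' Fit an ANFIS classifier to raw features
#'
#' Convenience wrapper: normalizes the inputs to \[0, 1\] (per-column
#' min/max from the training data), runs subtractive clustering on the
#' joint input(+output) space, initializes the FIS and trains it.
#'
#' @param X numeric feature matrix or data.frame (an `ex_id` column is
#'   ignored).
#' @param y numeric labels 1..6.
#' @param config an [anfis_config()].
#' @return A trained `fis` (with `norm` scaling stored) whose attribute
#'   `report` is the training report.
#' @export
fit_anfis <- function(X, y, config = anfis_config()) {
  X <- .as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  xmin <- apply(X, 2, min)
  xrange <- apply(X, 2, max) - xmin
  xrange[xrange == 0] <- 1
  Xn <- sweep(sweep(X, 2, xmin), 2, xrange, "/")
  cl_data <- Xn
  if (config$include_output) {
    yr <- range(y)
    yspan <- if (diff(yr) == 0) 1 else diff(yr)
    cl_data <- cbind(Xn, (y - yr[1]) / yspan)
  }
  centers <- subtractive_cluster(cl_data, config)
  fis <- init_fis(centers, Xn, y, config)
  trained <- train_anfis(fis, Xn, y, epochs = config$epochs, config = config)
  fis <- trained$fis
  fis$norm <- list(min = xmin, range = xrange,
                   feature_names = colnames(X))
  attr(fis, "report") <- trained$report
  fis
}

#' Weighted-average defuzzification for one input
#'
#' @param fis a trained `fis` (from [fit_anfis()], with normalization
#'   stored, or on already-normalized inputs).
#' @param x numeric feature vector on the raw feature scale.
#' @param min_weight rule-activation floor; if every rule fires below it
#'   the input is outside the membership support and an error of class
#'   `rehabrecog_out_of_range` is raised.
#' @return The crisp output value.
#' @export
infer_crisp <- function(fis, x, min_weight = 1e-12) {
  stopifnot(inherits(fis, "fis"))
  xn <- .anfis_normalize(fis, matrix(x, nrow = 1))
  out <- .fis_eval(fis, xn, min_weight = min_weight)
  if (is.na(out)) {
    stop(structure(class = c("rehabrecog_out_of_range", "error", "condition"),
                   list(message = "input outside the membership-function inferring range",
                        call = sys.call())))
  }
  as.numeric(out)
}

#' Crisp ANFIS outputs for a feature matrix
#'
#' @inheritParams infer_crisp
#' @param X feature matrix or data.frame (raw scale).
#' @return Numeric vector of crisp outputs; inputs outside the membership
#'   support yield `NA` with a warning.
#' @export
predict_anfis <- function(fis, X, min_weight = 1e-12) {
  stopifnot(inherits(fis, "fis"))
  X <- .as_feature_matrix(X, expected = fis$norm$feature_names)
  out <- .fis_eval(fis, .anfis_normalize(fis, X), min_weight = min_weight)
  if (anyNA(out)) {
    warning(sum(is.na(out)),
            " input(s) outside the membership-function inferring range")
  }
  out
}

.anfis_normalize <- function(fis, X) {
  if (is.null(fis$norm)) return(X)
  sweep(sweep(X, 2, fis$norm$min), 2, fis$norm$range, "/")
}

#' Decode a crisp output to an exercise label
#'
#' Round half up to the nearest integer, clamped to \[1, 6\]: a crisp value
#' in \[k - 0.5, k + 0.4\] (and up to just below k + 0.5) decodes to label
#' k, e.g. 0.9 -> 1, 1.75 -> 2.
#'
#' @param v numeric crisp value(s); must be finite.
#' @return Integer label(s) in 1..6.
#' @export
crisp_to_label <- function(v) {
  if (any(!is.finite(v))) stop("non-finite crisp value", call. = FALSE)
  pmin(pmax(as.integer(floor(v + 0.5)), 1L), 6L)
}

#' @export
print.fis <- function(x, ...) {
  cat(sprintf("Sugeno FIS: %d rule(s), %d input(s), %s consequents\n",
              nrow(x$centers), ncol(x$centers), x$consequent))
  invisible(x)
}
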