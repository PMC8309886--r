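# Empirical mode decomposition.
#
# Sifting splits a signal into intrinsic mode functions (IMFs): oscillatory
# components whose numbers of extrema and zero crossings differ by at most
# one and whose local mean (the average of the cubic-spline envelopes through
# the maxima and minima) is near zero. The residue after extracting the IMFs
# is monotonic-like (fewer than 3 extrema). Decomposition is exact by
# construction: sum(IMFs) + residue == input.

# indices of strict local maxima/minima; plateaus contribute their midpoint
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  s <- sign(d)
  if (all(s == 0)) return(list(max = integer(0), min = integer(0)))
  last <- 0
  plateau_start <- 0L
  maxi <- integer(0); mini <- integer(0)
  for (i in seq_len(n - 1)) {
    if (s[i] == 0) {
      if (plateau_start == 0L) plateau_start <- i
      next
    }
    if (last != 0 && s[i] != last) {
      at <- if (plateau_start > 0L) (plateau_start + i) %/% 2L else i
      if (last > 0) maxi <- c(maxi, at) else mini <- c(mini, at)
    }
    last <- s[i]
    plateau_start <- 0L
  }
  list(max = maxi, min = mini)
}

.n_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Upper, lower and mean envelopes of a signal
#'
#' Interpolates cubic splines through the local maxima (upper) and minima
#' (lower). Two extrema are mirror-extended at each end to curb end
#' effects. Signals with fewer than 2 maxima or 2 minima are
#' "monotonic-like" and cannot be sifted.
#'
#' @param x numeric signal.
#' @return A list with `upper`, `lower`, `mean` (numeric, same length as
#'   `x`), or `NULL` if there are too few extrema.
#' @export
envelopes <- function(x) {
  n <- length(x)
  ext <- .local_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NULL)
  upper <- .spline_envelope(ext$max, x[ext$max], n)
  lower <- .spline_envelope(ext$min, x[ext$min], n)
  list(upper = upper, lower = lower, mean = (upper + lower) / 2)
}

# cubic spline through (idx, val) with two mirrored extrema at each end
.spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  m <- min(2L, k)
  pre_i <- 2 - idx[seq_len(m)]            # first extrema mirrored about sample 1
  pre_v <- val[seq_len(m)]
  post_i <- 2 * n - idx[(k - m + 1):k]    # last extrema mirrored about sample n
  post_v <- val[(k - m + 1):k]
  xs <- c(rev(pre_i), idx, rev(post_i))
  ys <- c(rev(pre_v), val, rev(post_v))
  keep <- !duplicated(xs)
  f <- stats::splinefun(xs[keep], ys[keep], method = "fmm")
  f(seq_len(n))
}

#' Sift one intrinsic mode function out of a signal
#'
#' Repeatedly subtracts the mean envelope from the candidate until (a) the
#' numbers of extrema and zero crossings differ by at most one and (b) the
#' normalized squared change between successive candidates (the Cauchy
#' criterion `sum((prev-cur)^2)/sum(prev^2)`) falls below `sd_tol`, or
#' `max_sift` iterations are reached.
#'
#' @param x numeric signal with at least 2 maxima and 2 minima.
#' @param sd_tol Cauchy stopping tolerance (default 0.25).
#' @param max_sift maximum sifting iterations (default 100).
#' @return The IMF (numeric). Attribute `converged` is `FALSE` when
#'   `max_sift` was exhausted (a warning is also raised); `NULL` when the
#'   signal is monotonic-like.
#' @export
sift <- function(x, sd_tol = 0.25, max_sift = 100) {
  h <- x
  for (it in seq_len(max_sift)) {
    env <- envelopes(h)
    if (is.null(env)) {
      # over-sifted down to a monotonic-like remainder: return as-is
      return(structure(h, converged = TRUE))
    }
    h_new <- h - env$mean
    ext <- .local_extrema(h_new)
    n_ext <- length(ext$max) + length(ext$min)
    n_zc <- .n_zero_crossings(h_new)
    sd <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    ok <- abs(n_ext - n_zc) <= 1 && sd < sd_tol
    h <- h_new
    if (ok) return(structure(h, converged = TRUE))
  }
  warning("sifting did not converge within max_sift iterations")
  structure(h, converged = FALSE)
}

#' Empirical mode decomposition
#'
#' Extracts IMFs by repeated sifting until the residue is monotonic-like
#' (fewer than 3 extrema) or `max_imfs` IMFs have been produced.
#'
#' @param x numeric signal, length >= 8.
#' @param max_imfs maximum number of IMFs (default 3; slow cyclic motions
#'   carry no useful structure beyond the first few modes).
#' @param sd_tol,max_sift passed to [sift()].
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors, fastest mode first), `residue`, and `signal` (the input).
#'   `sum(imfs) + residue` reproduces the input to floating-point accuracy.
#' @export
emd <- function(x, max_imfs = 3, sd_tol = 0.25, max_sift = 100) {
  stopifnot(length(x) >= 8, max_imfs >= 1)
  residue <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ext <- .local_extrema(residue)
    if (length(ext$max) + length(ext$min) < 3) break
    if (length(ext$max) < 2 || length(ext$min) < 2) break
    imf <- sift(residue, sd_tol = sd_tol, max_sift = max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- as.numeric(imf)
    residue <- residue - as.numeric(imf)
  }
  structure(list(imfs = imfs, residue = residue, signal = x),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d IMF(s) + residue over %d samples\n",
              length(x$imfs), length(x$signal)))
  invisible(x)
}
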