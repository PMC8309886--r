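# Feature extraction from relative-angle segments.
#
# Each labeled segment (one exercise cycle, n x 3 relative angles) is
# summarized by 21 features per axis: 15 time-domain statistics plus the 6
# marginal-Hilbert-spectrum centroid features of the first three IMFs,
# giving a 63-entry feature vector. Fifteen fixed feature patterns (subsets
# of the 63 keys) are the candidate inputs of the recognizers.

.time_symbols <- c("sum", "abs_sum", "sqr_sum", "avg", "abs_avg", "median",
                   "quart", "min", "max", "range", "abs_dev_avg", "std_dev",
                   "var", "skrew", "kurt")
.freq_symbols <- c("IMF1_f", "IMF2_f", "IMF3_f", "IMF1_e", "IMF2_e", "IMF3_e")
.all_symbols <- c(.time_symbols, .freq_symbols)

#' The 63 feature keys
#'
#' Axis-major ordering: the 21 per-axis symbols for x, then y, then z.
#' @return Character vector of length 63, e.g. `"xsum"`, `"yIMF3_e"`.
#' @export
feature_keys <- function() {
  as.vector(vapply(c("x", "y", "z"),
                   function(a) paste0(a, .all_symbols), character(21)))
}

#' Time-domain features of one axis series
#'
#' The 15 per-axis time-domain statistics: sum, sum of absolute values, sum
#' of squares, mean, mean of absolute values, median, quartile distance
#' (Q3 - Q1, interpolated quantiles), min, max, range, mean absolute
#' deviation, population standard deviation and variance (1/n), and the
#' standardized skewness and kurtosis
#' `SK = mean(((x - mu)/sigma)^3)`, `KT = mean(((x - mu)/sigma)^4)`.
#' A degenerate (constant) series has `sigma = 0`; its skewness and
#' kurtosis are returned as 0 with a warning.
#'
#' @param x numeric series (one axis of a segment), length >= 2.
#' @return Named numeric of length 15 (names as in [feature_keys()] without
#'   the axis prefix).
#' @export
time_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  mu <- mean(x)
  dev <- x - mu
  v <- mean(dev^2)           # population variance
  sd_ <- sqrt(v)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (sd_ == 0) {
    warning("constant series: skewness and kurtosis set to 0")
    sk <- 0
    kt <- 0
  } else {
    sk <- mean((dev / sd_)^3)
    kt <- mean((dev / sd_)^4)
  }
  stats::setNames(
    c(sum(x), sum(abs(x)), sum(x^2), mu, mean(abs(x)), stats::median(x),
      q[2] - q[1], min(x), max(x), max(x) - min(x), mean(abs(dev)),
      sd_, v, sk, kt),
    .time_symbols
  )
}

#' Full 63-entry feature vector of a segment
#'
#' Concatenates, per axis (x, y, z), the 15 time-domain features and the 6
#' HHT marginal-spectrum centroid features.
#'
#' @param segment an `angle_segment` from [segment_stream()] (n x 3 relative
#'   angles with `exercise_id` and `sample_rate` attributes), or a plain
#'   n x 3 matrix plus `sample_rate`.
#' @param hht_cfg an [hht_config()].
#' @param sample_rate Hz; taken from the segment attribute when present.
#' @return Named numeric of length 63 with attribute `exercise_id` copied
#'   from the segment.
#' @export
feature_vector <- function(segment, hht_cfg = hht_config(),
                           sample_rate = attr(segment, "sample_rate")) {
  seg <- as.matrix(segment)
  stopifnot(ncol(seg) == 3, !is.null(sample_rate))
  out <- numeric(0)
  for (a in 1:3) {
    x <- seg[, a]
    tf <- time_features(x)
    ff <- hht_features(x, sample_rate, cfg = hht_cfg)
    out <- c(out, tf, ff)
  }
  names(out) <- feature_keys()
  attr(out, "exercise_id") <- attr(segment, "exercise_id")
  out
}

#' Feature table of a list of segments
#'
#' @param segments list of `angle_segment`.
#' @param hht_cfg an [hht_config()].
#' @return data.frame with the 63 feature columns plus `ex_id`.
#' @export
feature_table <- function(segments, hht_cfg = hht_config()) {
  rows <- lapply(segments, function(s) {
    fv <- suppressWarnings(feature_vector(s, hht_cfg = hht_cfg))
    c(fv, ex_id = as.numeric(attr(s, "exercise_id")))
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$ex_id <- as.integer(df$ex_id)
  df
}

#' Write / read a feature table as CSV
#'
#' One row per segment, the 63 feature columns plus `ex_id`.
#' @param features data.frame from [feature_table()].
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c(feature_keys(), "ex_id") %in% names(df)))
  df
}

#' The fifteen feature patterns
#'
#' Fixed subsets of the 63 feature keys used as recognizer inputs:
#' (1) all 63; (2) all 18 frequency-domain features; (3) y/z sums;
#' (4) y/z absolute sums; (5) union of 3 and 4; (6) y/z means;
#' (7) y/z absolute means; (8) union of 6 and 7; (9)-(11) frequency and
#' energy of IMF1/IMF2/IMF3 on all axes; (12) pattern 8 plus the IMF3
#' features on y/z; (13)-(15) all 21 features of a single axis.
#'
#' @return Named list `pattern_id -> character vector of keys`.
#' @export
feature_patterns <- function() {
  yz <- function(sym) as.vector(t(outer(c("y", "z"), sym, paste0)))
  xyz_imf <- function(j) {
    as.vector(vapply(c("x", "y", "z"),
                     function(a) paste0(a, "IMF", j, c("_f", "_e")),
                     character(2)))
  }
  keys <- feature_keys()
  list(
    `1` = keys,
    `2` = as.vector(vapply(c("x", "y", "z"),
                           function(a) paste0(a, .freq_symbols), character(6))),
    `3` = c("ysum", "zsum"),
    `4` = c("yabs_sum", "zabs_sum"),
    `5` = c("ysum", "zsum", "yabs_sum", "zabs_sum"),
    `6` = c("yavg", "zavg"),
    `7` = c("yabs_avg", "zabs_avg"),
    `8` = c("yavg", "yabs_avg", "zavg", "zabs_avg"),
    `9` = xyz_imf(1),
    `10` = xyz_imf(2),
    `11` = xyz_imf(3),
    `12` = c("yavg", "zavg", "yabs_avg", "zabs_avg",
             "yIMF3_f", "zIMF3_f", "yIMF3_e", "zIMF3_e"),
    `13` = paste0("x", .all_symbols),
    `14` = paste0("y", .all_symbols),
    `15` = paste0("z", .all_symbols)
  )
}

#' Select a feature pattern from a feature vector or table
#'
#' @param fv a named 63-entry feature vector, or a [feature_table()]
#'   data.frame.
#' @param pattern_id integer 1..15.
#' @return The sub-vector (or sub-data.frame, `ex_id` retained) in the
#'   pattern's declared key order.
#' @export
select_pattern <- function(fv, pattern_id) {
  pats <- feature_patterns()
  key <- as.character(pattern_id)
  if (length(pattern_id) != 1 || !key %in% names(pats)) {
    stop("`pattern_id` must be a single integer in 1..15", call. = FALSE)
  }
  cols <- pats[[key]]
  if (is.data.frame(fv)) {
    out <- fv[, c(cols, intersect("ex_id", names(fv))), drop = FALSE]
    return(out)
  }
  fv[cols]
}
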