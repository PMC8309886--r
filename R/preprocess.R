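# Tilt-angle preprocessing.
#
# The accelerometer of a quasi-statically moving sensor reads the gravity
# direction in the sensor frame, so sensor orientation can be summarized by
# tilt angles derived from the acceleration components. Two conventions are
# supported: the inclinometer ("projected") angles
#   theta_i = atan(a_i / sqrt(a_j^2 + a_k^2))
# and the "included" angles between the acceleration vector and each base
# axis, theta_i = asin(a_i / |a|). Downstream stages use relative angles
# (measured minus initial posture), which makes the two conventions
# interchangeable for classification of planar motions.

.rad2deg <- 180 / pi

#' Projected (inclinometer) tilt angles
#'
#' `theta_x = atan(ax / sqrt(ay^2 + az^2))` (degrees), and analogously for y
#' and z. A zero denominator with a nonzero numerator yields +/-90 degrees
#' with the numerator's sign.
#'
#' @param a acceleration in g: a length-3 vector or an n x 3 matrix with
#'   columns ax, ay, az.
#' @return Angles in degrees, same shape as the input (columns
#'   `theta_x, theta_y, theta_z`), each in \[-90, 90\].
#' @export
tilt_projected <- function(a) {
  a <- .as_acc_matrix(a)
  th <- matrix(NA_real_, nrow(a), 3,
               dimnames = list(NULL, c("theta_x", "theta_y", "theta_z")))
  for (i in 1:3) {
    num <- a[, i]
    den <- sqrt(rowSums(a[, -i, drop = FALSE]^2))
    th[, i] <- ifelse(den == 0, sign(num) * 90, atan(num / den) * .rad2deg)
  }
  .drop_if_vector(th, a)
}

#' Included tilt angles
#'
#' `theta_i = asin(a_i / |a|)` (degrees): the angle between the acceleration
#' vector and the plane orthogonal to axis i. The three included angles
#' satisfy `sin^2(theta_x) + sin^2(theta_y) + sin^2(theta_z) = 1`.
#'
#' @inheritParams tilt_projected
#' @return Angles in degrees, same shape as the input, each in \[-90, 90\].
#' @export
tilt_included <- function(a) {
  a <- .as_acc_matrix(a)
  nrm <- sqrt(rowSums(a^2))
  u <- a / nrm
  u <- pmin(pmax(u, -1), 1)
  th <- asin(u) * .rad2deg
  colnames(th) <- c("theta_x", "theta_y", "theta_z")
  .drop_if_vector(th, a)
}

.as_acc_matrix <- function(a) {
  if (is.null(dim(a))) {
    stopifnot(length(a) == 3)
    a <- matrix(a, 1, 3)
    attr(a, "was_vector") <- TRUE
  }
  stopifnot(ncol(a) == 3)
  if (any(!is.finite(a))) stop("non-finite acceleration", call. = FALSE)
  if (any(rowSums(a^2) == 0)) {
    stop("zero acceleration vector: tilt angle undefined", call. = FALSE)
  }
  a
}

.drop_if_vector <- function(th, a) {
  if (isTRUE(attr(a, "was_vector"))) {
    out <- as.numeric(th)
    names(out) <- colnames(th)
    out
  } else {
    th[] <- as.numeric(th)  # strip helper attributes
    th
  }
}

#' Relative angles with respect to the initial posture
#'
#' Subtracts, per axis, the mean angle over the first `reference_window`
#' seconds (the rest posture) from every sample, removing inter-individual
#' posture offsets.
#'
#' @param angles n x 3 matrix of tilt angles (degrees) over time.
#' @param reference_window length of the initial reference window in
#'   seconds (default 0.5).
#' @param sample_rate sampling rate in Hz.
#' @return n x 3 matrix of relative angles (degrees).
#' @export
relativize <- function(angles, reference_window = 0.5, sample_rate = 100) {
  angles <- as.matrix(angles)
  if (nrow(angles) == 0) stop("empty angle series", call. = FALSE)
  m <- max(1L, round(reference_window * sample_rate))
  if (nrow(angles) <= m) {
    stop("series shorter than the reference window", call. = FALSE)
  }
  ref <- colMeans(angles[seq_len(m), , drop = FALSE])
  sweep(angles, 2, ref)
}

#' Cut a labeled stream into relative-angle segments
#'
#' Converts the acceleration channels of a motion stream to tilt angles
#' under the chosen convention, splits the stream into consecutive cycles of
#' `cycle_length * sample_rate` samples, relativizes each cycle against its
#' own initial rest window, and labels each segment with its exercise id.
#'
#' @param stream a `motion_stream`.
#' @param schedule the [build_schedule()] of the recorded exercise (defines
#'   the cycle length).
#' @param convention `"included"` (default) or `"projected"`.
#' @param reference_window seconds, passed to [relativize()].
#' @param drop_partial if `TRUE`, a trailing partial cycle is dropped;
#'   otherwise it is an error.
#' @return A list of `angle_segment` objects: n x 3 matrices of relative
#'   angles (degrees) with attributes `exercise_id` and `sample_rate`.
#' @export
segment_stream <- function(stream, schedule,
                           convention = c("included", "projected"),
                           reference_window = 0.5, drop_partial = FALSE) {
  convention <- match.arg(convention)
  stopifnot(inherits(schedule, "exercise_schedule"))
  sr <- attr(stream, "sample_rate")
  if (is.null(sr)) stop("stream lacks a sample_rate attribute", call. = FALSE)
  n_cycle <- round(schedule$cycle_length * sr)
  n <- nrow(stream)
  n_full <- n %/% n_cycle
  if (n %% n_cycle != 0) {
    if (!drop_partial) {
      stop("stream length is not a whole number of cycles ",
           "(use drop_partial = TRUE to truncate)", call. = FALSE)
    }
  }
  if (n_full < 1) stop("stream shorter than one cycle", call. = FALSE)

  tilt_fun <- if (convention == "included") tilt_included else tilt_projected
  acc <- as.matrix(stream[, c("ax", "ay", "az")])
  lapply(seq_len(n_full), function(i) {
    idx <- ((i - 1) * n_cycle + 1):(i * n_cycle)
    ang <- tilt_fun(acc[idx, , drop = FALSE])
    rel <- relativize(ang, reference_window, sr)
    lab <- stream$label[idx]
    lab <- if (all(is.na(lab))) NA_integer_ else as.integer(stats::median(lab, na.rm = TRUE))
    structure(rel, exercise_id = lab, sample_rate = sr,
              class = c("angle_segment", class(rel)))
  })
}

#' Segment a list of labeled cycles
#'
#' Applies [segment_stream()] to each generated cycle using the schedule of
#' its own label.
#'
#' @param cycles list of labeled `motion_stream` cycles (e.g. from
#'   [generate_dataset()]).
#' @param ... passed to [segment_stream()].
#' @return A flat list of `angle_segment` objects.
#' @export
segment_cycles <- function(cycles, ...) {
  unlist(lapply(cycles, function(cy) {
    segment_stream(cy, build_schedule(cy$label[1]), ...)
  }), recursive = FALSE)
}

#' Write relative-angle segments to CSV
#'
#' Long format, one row per (segment, axis, sample):
#' `segment,ex_id,axis,t,angle`.
#'
#' @param segments list of `angle_segment`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    sr <- attr(seg, "sample_rate")
    n <- nrow(seg)
    data.frame(
      segment = i,
      ex_id = attr(seg, "exercise_id"),
      axis = rep(c("x", "y", "z"), each = n),
      t = rep((0:(n - 1)) / sr, 3),
      angle = c(seg[, 1], seg[, 2], seg[, 3])
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
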