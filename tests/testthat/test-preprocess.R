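test_that("projected tilt angles follow the inclinometer formula", {
  expect_equal(tilt_projected(c(0, 0, 1)), c(theta_x = 0, theta_y = 0, theta_z = 90))
  # zero denominator with nonzero numerator -> +/-90 with the numerator's sign
  expect_equal(tilt_projected(c(1, 0, 0)), c(theta_x = 90, theta_y = 0, theta_z = 0))
  expect_equal(tilt_projected(c(-1, 0, 0))[["theta_x"]], -90)
  a <- c(0.5, 0.5, 0.7071)
  got <- tilt_projected(a)
  # direct arithmetic oracle
  expect_equal(got[["theta_x"]], atan(0.5 / sqrt(0.25 + 0.7071^2)) * 180 / pi)
  expect_equal(got[["theta_y"]], atan(0.5 / sqrt(0.25 + 0.7071^2)) * 180 / pi)
  expect_equal(got[["theta_z"]], atan(0.7071 / sqrt(0.5)) * 180 / pi)
  expect_error(tilt_projected(c(0, 0, 0)), "zero acceleration")
})

test_that("included tilt angles are asin components of the unit vector", {
  expect_equal(tilt_included(c(0, 0.5, 0.8660254))[["theta_y"]], 30)
  expect_equal(tilt_included(c(0, 0, 1)), c(theta_x = 0, theta_y = 0, theta_z = 90))
  expect_error(tilt_included(c(0, 0, 0)), "zero acceleration")
  # identity: sin^2 components of a unit vector sum to 1
  set.seed(3)
  for (i in 1:25) {
    v <- rnorm(3)
    th <- tilt_included(v) * pi / 180
    expect_equal(sum(sin(th)^2), 1, tolerance = 1e-9)
  }
})

test_that("relativization subtracts the initial rest posture", {
  const <- matrix(10, 200, 3)
  expect_true(all(relativize(const) == 0))
  x <- matrix(10, 200, 3)
  x[101:200, 2] <- 40
  rel <- relativize(x, reference_window = 0.5, sample_rate = 100)
  expect_equal(max(rel[, 2]), 30)
  # noisy rest window: the relative mean over the window is 0
  set.seed(8)
  noisy <- matrix(rnorm(600, 10), 200, 3)
  reln <- relativize(noisy, 0.5, 100)
  expect_equal(colMeans(reln[1:50, ]), c(0, 0, 0), tolerance = 1e-9)
  expect_error(relativize(matrix(numeric(0), 0, 3)), "empty")
})

test_that("streams are cut into labeled 1100x3 relative-angle segments", {
  prof <- subject_profile(seed = 2L)
  stream <- bind_streams(replicate(3, generate_cycle(build_schedule(2), prof),
                                   simplify = FALSE))
  segs <- segment_stream(stream, build_schedule(2))
  expect_length(segs, 3)
  for (s in segs) {
    expect_equal(dim(s), c(1100, 3))
    expect_equal(attr(s, "exercise_id"), 2L)
  }
  # partial trailing cycle: error unless explicitly dropped
  part <- stream[1:1650, ]
  attr(part, "sample_rate") <- 100
  class(part) <- class(stream)
  expect_error(segment_stream(part, build_schedule(2)), "whole number")
  expect_length(segment_stream(part, build_schedule(2), drop_partial = TRUE), 1)
})

test_that("segmenting a concatenated stream matches per-cycle segmentation", {
  prof <- subject_profile(seed = 6L)
  cycles <- generate_dataset(2, prof)[1:3]
  from_bind <- segment_stream(bind_streams(cycles), build_schedule(1))
  per_cycle <- unlist(lapply(cycles, segment_stream, schedule = build_schedule(1)),
                      recursive = FALSE)
  for (i in 1:3) {
    expect_equal(unclass(from_bind[[i]]), unclass(per_cycle[[i]]),
                 ignore_attr = TRUE)
  }
})

test_that("both angle conventions rank the classes identically on noiseless data", {
  prof <- quiet_profile()
  cycles <- generate_dataset(1, prof)
  mean_zsum <- function(convention) {
    vapply(segment_cycles(cycles, convention = convention),
           function(s) sum(s[, 3]), 0)
  }
  mean_ysum <- function(convention) {
    vapply(segment_cycles(cycles, convention = convention),
           function(s) sum(s[, 2]), 0)
  }
  # compare rankings among the exercises that actually move on each axis
  # (for the others the aggregate is numerical dust with arbitrary rank)
  moving_z <- 2:6
  moving_y <- c(1, 2, 4, 6)
  expect_equal(rank(mean_zsum("included")[moving_z]),
               rank(mean_zsum("projected")[moving_z]))
  expect_equal(rank(mean_ysum("included")[moving_y]),
               rank(mean_ysum("projected")[moving_y]))
})
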