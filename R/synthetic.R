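# Synthetic wearable-IMU motion generator.
#
# Emulates a single 6-axis inertial sensor worn on the lower limb while the
# subject performs one of the six scheduled exercises. The model is
# quasi-static: the limb moves slowly enough that the accelerometer reads
# (essentially) the gravity direction in the sensor frame, so with zero noise
# the acceleration norm is exactly 1 g at every sample. Each exercise tilts
# the sensor along a fixed (y, z) direction ("axis mix") by a smooth
# rest-rise-hold-return angle trajectory; the gyroscope reads the angle
# derivatives. Sensor noise, cycle-to-cycle range-of-motion variability,
# phase-timing jitter and a small physiological tremor are superposed.

# per-exercise defaults: peak relative angle (deg) on the mixed axis and the
# unit (y, z) direction of the tilt; chosen so that the six classes occupy
# distinct regions of the (y-sum, z-sum) feature plane, as slow planar
# lower-limb exercises do
.default_rom <- c(60, 35, 70, 45, 28, 20)
.default_axis_mix <- rbind(
  c(1, 0),
  c(0.7071068, 0.7071068),
  c(0, 1),
  c(0.6, -0.8),
  c(0, -1),
  c(-0.7071068, 0.7071068)
)
# initial rest posture: included angles (deg) on y and z before the motion
.default_rest_angles <- rbind(
  c(5, 3), c(-8, 4), c(2, -6), c(0, 8), c(4, 2), c(-3, -5)
)

#' Subject profile for the synthetic motion generator
#'
#' Bundles the subject-dependent generator parameters: per-exercise range of
#' motion (ROM), a global ROM multiplier emulating subject variability, the
#' per-exercise tilt direction in the (y, z) plane, sensor noise levels,
#' phase-timing jitter, a small tremor superposed on the motion, and the
#' random seed.
#'
#' @param rom_amplitude numeric length 6, peak relative tilt angle (degrees)
#'   per exercise along its mixed axis.
#' @param rom_scale unitless global ROM multiplier (subject variability).
#' @param rom_cycle_cv coefficient of variation of the per-cycle ROM draw
#'   (cycle-to-cycle variability around `rom_amplitude * rom_scale`).
#' @param axis_mix 6 x 2 matrix of unit (y, z) tilt directions, one row per
#'   exercise.
#' @param rest_angles 6 x 2 matrix of initial (y, z) included angles
#'   (degrees), the rest posture before the motion.
#' @param acc_noise_sd accelerometer noise SD in g.
#' @param gyro_noise_sd gyroscope noise SD in deg/s.
#' @param timing_jitter_sd SD (seconds) of the jitter applied to the phase
#'   boundaries inside a cycle; the total cycle length is kept fixed.
#' @param tremor_amp amplitude (degrees) of the sinusoidal tremor superposed
#'   on the motion envelope (it vanishes at rest).
#' @param tremor_freq tremor frequency in Hz.
#' @param seed integer seed used by [generate_dataset()].
#' @return An object of class `subject_profile` (a list of the above).
#' @export
subject_profile <- function(rom_amplitude = .default_rom,
                            rom_scale = 1,
                            rom_cycle_cv = 0.05,
                            axis_mix = .default_axis_mix,
                            rest_angles = .default_rest_angles,
                            acc_noise_sd = 0.01,
                            gyro_noise_sd = 0.5,
                            timing_jitter_sd = 0.1,
                            tremor_amp = 1,
                            tremor_freq = 1.5,
                            seed = 1L) {
  stopifnot(length(rom_amplitude) == 6, all(rom_amplitude >= 0),
            rom_scale > 0, rom_cycle_cv >= 0,
            is.matrix(axis_mix), all(dim(axis_mix) == c(6, 2)),
            is.matrix(rest_angles), all(dim(rest_angles) == c(6, 2)),
            acc_noise_sd >= 0, gyro_noise_sd >= 0, timing_jitter_sd >= 0,
            tremor_amp >= 0, tremor_freq > 0)
  norms <- sqrt(rowSums(axis_mix^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("each row of `axis_mix` must have unit norm", call. = FALSE)
  }
  structure(
    list(rom_amplitude = rom_amplitude, rom_scale = rom_scale,
         rom_cycle_cv = rom_cycle_cv, axis_mix = axis_mix,
         rest_angles = rest_angles, acc_noise_sd = acc_noise_sd,
         gyro_noise_sd = gyro_noise_sd, timing_jitter_sd = timing_jitter_sd,
         tremor_amp = tremor_amp, tremor_freq = tremor_freq,
         seed = seed),
    class = "subject_profile"
  )
}

# C1-continuous ramp on [0, 1]
.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# motion envelope s(t) in [0, 1] for phase boundaries b = (t1, t2, t3)
# (end of rest, end of rise, end of hold) within a cycle of length L
.motion_envelope <- function(t, b, L) {
  s <- numeric(length(t))
  rise <- t >= b[1] & t < b[2]
  hold <- t >= b[2] & t < b[3]
  ret  <- t >= b[3]
  s[rise] <- .smoothstep((t[rise] - b[1]) / (b[2] - b[1]))
  s[hold] <- 1
  s[ret]  <- 1 - .smoothstep((t[ret] - b[3]) / (L - b[3]))
  s
}

#' Generate one synthetic exercise cycle
#'
#' Simulates one cycle of a scheduled exercise under the quasi-static tilt
#' model. The per-axis included angles follow
#' `rest_angle + mix * (ROM * s(t) + tremor(t))` where `s(t)` is a
#' smoothstep rest-rise-hold-return envelope; the acceleration is the unit
#' gravity vector consistent with those included angles plus Gaussian noise,
#' and the gyroscope channels are the angle derivatives plus noise. Noise
#' and jitter draws are taken from the current RNG stream (seed the stream,
#' or use [generate_dataset()], for reproducibility).
#'
#' @param schedule an [build_schedule()] result.
#' @param profile a [subject_profile()].
#' @param sample_rate sampling rate in Hz (default 100).
#' @return A `motion_stream`: a data.frame with columns
#'   `t, ax, ay, az, gx, gy, gz, label` and attribute `sample_rate`.
#'   An 11-s cycle at 100 Hz has 1100 rows.
#' @export
generate_cycle <- function(schedule, profile, sample_rate = 100) {
  stopifnot(inherits(schedule, "exercise_schedule"),
            inherits(profile, "subject_profile"), sample_rate > 0)
  ex <- schedule$exercise_id
  L <- schedule$cycle_length
  n <- round(L * sample_rate)
  t <- (0:(n - 1)) / sample_rate

  d <- schedule$phases$duration
  b <- cumsum(d)[1:3]
  if (profile$timing_jitter_sd > 0) {
    b <- b + stats::rnorm(3, 0, profile$timing_jitter_sd)
    # keep phase ordering with a minimal phase length
    b <- pmin(pmax(b, c(0.2, 0.4, 0.6)), L - c(0.6, 0.4, 0.2))
    b <- sort(b)
    b[2] <- max(b[2], b[1] + 0.2)
    b[3] <- max(b[3], b[2] + 0.2)
  }

  rom <- profile$rom_amplitude[ex] * profile$rom_scale
  if (profile$rom_cycle_cv > 0 && rom > 0) {
    rom <- rom * (1 + stats::rnorm(1, 0, profile$rom_cycle_cv))
    rom <- max(rom, 0)
  }

  s <- .motion_envelope(t, b, L)
  tremor <- profile$tremor_amp * sin(2 * pi * profile$tremor_freq * t) * s
  theta <- rom * s + tremor             # angle along the mixed axis, deg

  mix <- profile$axis_mix[ex, ]
  ang_y <- profile$rest_angles[ex, 1] + mix[1] * theta
  ang_z <- profile$rest_angles[ex, 2] + mix[2] * theta

  sy <- sin(ang_y * pi / 180)
  sz <- sin(ang_z * pi / 180)
  sx2 <- 1 - sy^2 - sz^2
  if (any(sx2 < -1e-9)) {
    stop("infeasible posture: |sin(theta_y)|^2 + |sin(theta_z)|^2 > 1; ",
         "reduce ROM or rest angles", call. = FALSE)
  }
  sx <- sqrt(pmax(sx2, 0))
  ang_x <- asin(pmin(pmax(sx, -1), 1)) * 180 / pi

  # gyro = derivative of the included angles (deg/s), central differences
  deriv <- function(a) {
    n <- length(a)
    g <- numeric(n)
    g[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) * sample_rate / 2
    g[1] <- (a[2] - a[1]) * sample_rate
    g[n] <- (a[n] - a[n - 1]) * sample_rate
    g
  }

  acc <- cbind(sx, sy, sz)
  gyr <- cbind(deriv(ang_x), deriv(ang_y), deriv(ang_z))
  if (profile$acc_noise_sd > 0) {
    acc <- acc + matrix(stats::rnorm(3 * n, 0, profile$acc_noise_sd), n, 3)
  }
  if (profile$gyro_noise_sd > 0) {
    gyr <- gyr + matrix(stats::rnorm(3 * n, 0, profile$gyro_noise_sd), n, 3)
  }

  out <- data.frame(t = t,
                    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3],
                    label = ex)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("motion_stream", "data.frame")
  out
}

#' Generate a labeled synthetic dataset of exercise cycles
#'
#' Draws `n_per_exercise` cycles of each of the six exercises with the given
#' subject profile. The RNG is seeded from `profile$seed`, so the output is
#' reproducible bit-for-bit.
#'
#' @param n_per_exercise cycles per exercise (>= 1).
#' @inheritParams generate_cycle
#' @return A list of `6 * n_per_exercise` labeled `motion_stream` cycles,
#'   ordered by exercise then repetition.
#' @export
generate_dataset <- function(n_per_exercise, profile = subject_profile(),
                             sample_rate = 100) {
  stopifnot(n_per_exercise >= 1)
  if (!is.null(profile$seed)) set.seed(profile$seed)
  cycles <- vector("list", 6L * n_per_exercise)
  k <- 0L
  for (ex in 1:6) {
    sch <- build_schedule(ex)
    for (i in seq_len(n_per_exercise)) {
      k <- k + 1L
      cycles[[k]] <- generate_cycle(sch, profile, sample_rate)
    }
  }
  cycles
}

#' Write / read a motion stream as CSV
#'
#' The interchange format for all downstream stages: header
#' `t,ax,ay,az,gx,gy,gz,label`, one row per sample, '.' decimal, UTF-8.
#' `label` is the exercise id (1..6) or empty for unlabeled samples.
#'
#' @param stream a `motion_stream` (or several rbind-ed cycles).
#' @param path file path.
#' @return `write_motion_csv` returns `path` invisibly; `read_motion_csv`
#'   returns a `motion_stream` with the sample rate inferred from the time
#'   stamps.
#' @export
write_motion_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop("motion CSV must have columns t,ax,ay,az,gx,gy,gz[,label]",
         call. = FALSE)
  }
  if (is.null(df$label)) df$label <- NA_integer_
  dt <- diff(df$t[1:min(50, nrow(df))])
  attr(df, "sample_rate") <- 1 / stats::median(dt)
  class(df) <- c("motion_stream", "data.frame")
  df
}

#' Concatenate several cycles into one continuous stream
#'
#' @param cycles list of `motion_stream` cycles with a common sample rate.
#' @return One `motion_stream` with consecutive time stamps.
#' @export
bind_streams <- function(cycles) {
  stopifnot(length(cycles) >= 1)
  sr <- attr(cycles[[1]], "sample_rate")
  dfs <- lapply(cycles, as.data.frame)
  n_before <- c(0, cumsum(vapply(dfs, nrow, 0L)))
  for (i in seq_along(dfs)) dfs[[i]]$t <- (n_before[i] + seq_len(nrow(dfs[[i]])) - 1) / sr
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  attr(out, "sample_rate") <- sr
  class(out) <- c("motion_stream", "data.frame")
  out
}
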