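# Motion-guide schedules for the six lower-limb exercises.
#
# Every exercise cycle is decomposed into four scheduled phases
# (initial rest posture, rise to the target posture, hold, return)
# whose durations sum to an 11-s cycle.

# phase durations (s) per exercise, rows: rest, rise, hold, return
.schedule_durations <- list(
  `1` = c(2, 2, 5, 2),
  `2` = c(4, 1, 5, 1),
  `3` = c(2, 2, 5, 2),
  `4` = c(2, 2, 5, 2),
  `5` = c(4, 1, 5, 1),
  `6` = c(4, 1, 5, 1)
)

.exercise_names <- c(
  "iliopsoas", "gluteus medius", "quadriceps femoris",
  "hamstrings", "tibialis anterior", "triceps surae"
)

#' Build the motion-guide schedule for one exercise
#'
#' Returns the four-phase decomposition (rest, rise, hold, return) of one
#' exercise cycle. All six exercises are scheduled as 11-s cycles; the rise
#' and return ramps are short (1-2 s) and the target posture is held for 5 s.
#'
#' @param exercise_id integer in 1..6 (1 iliopsoas, 2 gluteus medius,
#'   3 quadriceps femoris, 4 hamstrings, 5 tibialis anterior,
#'   6 triceps surae).
#' @return An object of class `exercise_schedule`: a list with
#'   `exercise_id`, `exercise_name`, `phases` (data.frame with `phase` and
#'   `duration` in seconds) and `cycle_length` (seconds).
#' @examples
#' sch <- build_schedule(1)
#' sch$cycle_length  # 11
#' @export
build_schedule <- function(exercise_id) {
  if (length(exercise_id) != 1L || is.na(exercise_id) ||
      exercise_id %% 1 != 0 || exercise_id < 1 || exercise_id > 6) {
    stop("`exercise_id` must be a single integer in 1..6", call. = FALSE)
  }
  durations <- .schedule_durations[[as.character(exercise_id)]]
  phases <- data.frame(
    phase = c("rest", "rise", "hold", "return"),
    duration = durations,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      exercise_id = as.integer(exercise_id),
      exercise_name = .exercise_names[exercise_id],
      phases = phases,
      cycle_length = sum(durations)
    ),
    class = "exercise_schedule"
  )
}

#' @export
print.exercise_schedule <- function(x, ...) {
  cat(sprintf("Exercise %d (%s): %g-s cycle\n",
              x$exercise_id, x$exercise_name, x$cycle_length))
  for (i in seq_len(nrow(x$phases))) {
    cat(sprintf("  %-6s %g s\n", x$phases$phase[i], x$phases$duration[i]))
  }
  invisible(x)
}
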