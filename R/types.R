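# Session data model. A session set is one participant-day-set unit: the
# dynamometer ground truth plus one execution of each of the three
# touchscreen tasks. Streams are plain data frames; constructors validate
# the invariants the rest of the pipeline relies on.

SENSOR_CHANNELS <- c("accel_x", "accel_y", "accel_z",
                     "gyro_x",  "gyro_y",  "gyro_z",
                     "orient_x", "orient_y", "orient_z")

TASK_TYPES <- c("tap", "flick", "drag")

#' Grip strength ground truth for one set
#'
#' Two consecutive dynamometer readings; the ground truth used as the
#' regression target is their arithmetic mean and is always derived, never
#' stored independently.
#'
#' @param reading_1,reading_2 dynamometer readings in kg (finite, >= 0).
#' @return A `grip_measurement` with derived `ground_truth`.
#' @export
grip_measurement <- function(reading_1, reading_2) {
  if (!is.finite(reading_1) || !is.finite(reading_2) ||
      reading_1 < 0 || reading_2 < 0)
    stopf("grip readings must be finite and >= 0 (got %s, %s)",
          format(reading_1), format(reading_2))
  structure(list(reading_1 = reading_1, reading_2 = reading_2,
                 ground_truth = (reading_1 + reading_2) / 2),
            class = "grip_measurement")
}

#' One execution of a touchscreen task
#'
#' @param task `"tap"`, `"flick"`, or `"drag"`.
#' @param sub_events data frame with columns `index`, `t_appear`, `t_input`,
#'   `target_x`, `target_y`, `success`. Tap and flick carry exactly 10
#'   sub-events, drag exactly 1.
#' @param touch data frame with columns `t` (s since task start), `x`, `y`
#'   (mm, top-left origin), `phase` (`down`/`move`/`up`), `contact_area`
#'   (device-normalized, >= 0).
#' @param sensor data frame with column `t` plus the nine inertial channels
#'   `accel_x..z` (m/s^2), `gyro_x..z` (rad/s), `orient_x..z` (degrees),
#'   nominally sampled at 60 Hz.
#' @param elapsed total task duration in seconds (> 0).
#' @param spiral optional [spiral_spec()] attached to drag executions.
#' @return A `task_execution`.
#' @export
task_execution <- function(task, sub_events, touch, sensor, elapsed,
                           spiral = NULL) {
  task <- match.arg(task, TASK_TYPES)
  expected <- if (task == "drag") 1L else 10L
  if (nrow(sub_events) != expected)
    stopf("%s execution must have %d sub-events, got %d",
          task, expected, nrow(sub_events))
  if (any(sub_events$t_input < sub_events$t_appear))
    stopf("%s execution: t_input earlier than t_appear", task)
  if (!all(c("t", "x", "y", "phase", "contact_area") %in% names(touch)))
    stopf("touch stream missing required columns")
  if (is.unsorted(touch$t)) stopf("touch stream not sorted by t")
  if (any(touch$t < 0)) stopf("negative touch timestamps")
  if (any(touch$contact_area < 0)) stopf("negative contact area")
  if (!all(c("t", SENSOR_CHANNELS) %in% names(sensor)))
    stopf("sensor stream missing required columns")
  if (is.unsorted(sensor$t)) stopf("sensor stream not sorted by t")
  if (!is.finite(elapsed) || elapsed <= 0) stopf("elapsed must be > 0")
  out <- structure(list(task = task, sub_events = sub_events, touch = touch,
                        sensor = sensor, elapsed = elapsed),
                   class = "task_execution")
  if (!is.null(spiral)) attr(out, "spiral") <- spiral
  out
}

#' One participant-day-set unit
#'
#' @param participant_id opaque participant label.
#' @param day 1-based study day.
#' @param set_index set number within the day (1..10 in the study design).
#' @param grip a [grip_measurement()].
#' @param executions named list with exactly the elements `tap`, `flick`,
#'   `drag`, each a [task_execution()] of the matching type.
#' @param hand `"left"` or `"right"`.
#' @param handedness `"dominant"` or `"nondominant"`.
#' @return A `session_set`.
#' @export
session_set <- function(participant_id, day, set_index, grip, executions,
                        hand = "right", handedness = "dominant") {
  stopifnot(is_count(day), is_count(set_index))
  if (!inherits(grip, "grip_measurement")) stopf("grip must be a grip_measurement")
  if (!setequal(names(executions), TASK_TYPES))
    stopf("executions must be named tap, flick, drag")
  for (tk in TASK_TYPES) {
    ex <- executions[[tk]]
    if (!inherits(ex, "task_execution") || ex$task != tk)
      stopf("executions$%s is not a %s task_execution", tk, tk)
  }
  hand <- match.arg(hand, c("left", "right"))
  handedness <- match.arg(handedness, c("dominant", "nondominant"))
  structure(list(participant_id = as.character(participant_id),
                 day = as.integer(day), set_index = as.integer(set_index),
                 grip = grip, executions = executions[TASK_TYPES],
                 hand = hand, handedness = handedness),
            class = "session_set")
}

# Validate one session set against screen bounds; names the offending record.
validate_session_set <- function(set, screen = screen_spec()) {
  where <- sprintf("participant %s day %d set %d",
                   set$participant_id, set$day, set$set_index)
  for (tk in TASK_TYPES) {
    tch <- set$executions[[tk]]$touch
    if (nrow(tch) > 0 &&
        (any(tch$x < -1e-9) || any(tch$x > screen$width_mm + 1e-9) ||
         any(tch$y < -1e-9) || any(tch$y > screen$height_mm + 1e-9)))
      stopf("validation error (%s, %s task): touch coordinates outside %.1f x %.1f mm screen",
            where, tk, screen$width_mm, screen$height_mm)
  }
  invisible(TRUE)
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> participant %s, day %d, set %d (%s hand)\n",
              x$participant_id, x$day, x$set_index, x$hand))
  cat(sprintf("  grip: %.1f / %.1f kg -> ground truth %.2f kg\n",
              x$grip$reading_1, x$grip$reading_2, x$grip$ground_truth))
  for (tk in TASK_TYPES) {
    ex <- x$executions[[tk]]
    cat(sprintf("  %-5s %4.1f s, %3d touch samples, %3d sensor frames\n",
                tk, ex$elapsed, nrow(ex$touch), nrow(ex$sensor)))
  }
  invisible(x)
}
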