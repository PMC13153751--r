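# Feature extraction. One execution of a task yields one feature vector;
# behavioral quantities are aggregated over the 10 sub-events (tap, flick)
# by their mean, and every anchor contributes 99 windowed sensor statistics
# (9 channels x {pre, post} x {max, min, range, mean, mean |frame diff|}
# plus the 9 during-input channel values), averaged over anchors.

sensor_stat_names <- function() {
  pp <- as.vector(outer(
    SENSOR_CHANNELS,
    c("max", "min", "range", "mean", "diffmean"),
    function(ch, st) paste("sens", ch, st, sep = "_")))
  c(paste0("pre_", pp), paste0("post_", pp),
    paste("sens", SENSOR_CHANNELS, "during", sep = "_"))
}

#' Windowed sensor statistics for one input event
#'
#' For each inertial channel and each of the pre/post windows: the maximum,
#' minimum, range, mean, and the mean absolute consecutive-frame difference
#' (rate of change); plus the nine during-input channel values. 99 values.
#'
#' @param windows an `event_windows` from [extract_windows()].
#' @return Named numeric vector of 99 statistics.
#' @export
sensor_stats <- function(windows) {
  stat_block <- function(m) {
    n <- nrow(m)
    mx <- m[1, ]; mn <- m[1, ]
    for (r in seq_len(n)[-1]) {
      mx <- pmax(mx, m[r, ]); mn <- pmin(mn, m[r, ])
    }
    dm <- colMeans(abs(m[-1, , drop = FALSE] - m[-n, , drop = FALSE]))
    c(t(rbind(mx, mn, mx - mn, colMeans(m), dm)))
  }
  out <- c(stat_block(windows$pre), stat_block(windows$post), windows$during)
  names(out) <- sensor_stat_names()
  out
}

# Split a touch stream into strokes (down ... up runs), in temporal order.
touch_strokes <- function(touch) {
  downs <- which(touch$phase == "down")
  ups <- which(touch$phase == "up")
  if (length(downs) != length(ups) || any(ups < downs))
    stopf("touch stream has unmatched down/up pairs")
  Map(function(d, u) touch[d:u, , drop = FALSE], downs, ups)
}

finish_features <- function(values, task_scope) {
  if (any(!is.finite(values)))
    stopf("non-finite feature value(s): %s",
          paste(names(values)[!is.finite(values)], collapse = ", "))
  structure(values, task_scope = task_scope, class = "grip_features")
}

# Windows for every sub-event anchor of an execution, on the preprocessed
# (interpolated + low-pass filtered) sensor stream.
event_windows_for <- function(execution, cutoff = 20, fs = 60) {
  sens <- lowpass(interpolate_missing(execution$sensor, fs), cutoff, fs)
  anchors <- if (execution$task == "drag") {
    (min(execution$touch$t) + max(execution$touch$t)) / 2
  } else execution$sub_events$t_input
  lapply(anchors, function(a) extract_windows(sens, a, fs = fs))
}

#' Tap-task features
#'
#' Per sub-event: spatial error (mm, tap point to target center), elimination
#' time (s, target shown to input), touch duration (s, down to up), and mean
#' contact area over the stroke; averaged over the 10 sub-events, plus the
#' mean windowed sensor statistics over the 10 input anchors.
#'
#' @param execution a tap `task_execution`.
#' @param windows list of `event_windows`, one per sub-event (default:
#'   computed from the execution's sensor stream after interpolation and
#'   20 Hz low-pass filtering).
#' @return A `grip_features` named vector.
#' @export
tap_features <- function(execution, windows = event_windows_for(execution)) {
  if (execution$task != "tap") stopf("tap_features needs a tap execution")
  strokes <- touch_strokes(execution$touch)
  if (length(strokes) != nrow(execution$sub_events))
    stopf("tap execution: %d strokes for %d sub-events",
          length(strokes), nrow(execution$sub_events))
  sub <- execution$sub_events
  per <- vapply(seq_along(strokes), function(i) {
    st <- strokes[[i]]
    c(spatial_error = sqrt((st$x[1] - sub$target_x[i])^2 +
                             (st$y[1] - sub$target_y[i])^2),
      elim_time = sub$t_input[i] - sub$t_appear[i],
      touch_duration = st$t[nrow(st)] - st$t[1],
      contact_area = mean(st$contact_area))
  }, numeric(4))
  beh <- rowMeans(per)
  names(beh) <- c("spatial_error_mm", "elim_time_s", "touch_duration_s",
                  "contact_area")
  sens <- rowMeans(vapply(windows, sensor_stats,
                          numeric(length(sensor_stat_names()))))
  finish_features(c(beh, sens), "tap")
}

#' Flick-task features
#'
#' Per sub-event: flick direction as the unit vector from the first to the
#' last touch sample of the stroke (x and y components in screen
#' coordinates), elimination time, stroke duration, and mean contact area;
#' averaged over sub-events, plus mean windowed sensor statistics.
#' Zero-length strokes have no direction; they are excluded from the
#' aggregate and counted in the `n_excluded` attribute.
#'
#' @inheritParams tap_features
#' @param execution a flick `task_execution`.
#' @return A `grip_features` named vector.
#' @export
flick_features <- function(execution, windows = event_windows_for(execution)) {
  if (execution$task != "flick") stopf("flick_features needs a flick execution")
  strokes <- touch_strokes(execution$touch)
  if (length(strokes) != nrow(execution$sub_events))
    stopf("flick execution: %d strokes for %d sub-events",
          length(strokes), nrow(execution$sub_events))
  sub <- execution$sub_events
  rows <- lapply(seq_along(strokes), function(i) {
    st <- strokes[[i]]
    dx <- st$x[nrow(st)] - st$x[1]
    dy <- st$y[nrow(st)] - st$y[1]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) return(NULL)  # direction undefined
    c(dir_x = dx / len, dir_y = dy / len,
      elim_time = sub$t_input[i] - sub$t_appear[i],
      stroke_duration = st$t[nrow(st)] - st$t[1],
      contact_area = mean(st$contact_area))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stopf("flick execution: every stroke has zero length")
  beh <- rowMeans(do.call(cbind, rows[keep]))
  names(beh) <- c("dir_x", "dir_y", "elim_time_s", "stroke_duration_s",
                  "contact_area")
  sens <- rowMeans(vapply(windows[keep], sensor_stats,
                          numeric(length(sensor_stat_names()))))
  out <- finish_features(c(beh, sens), "flick")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Drag-task features
#'
#' Tracing accuracy (mean distance from each touch sample to the nearest
#' point on the reference spiral centerline), speed and acceleration
#' magnitude (mean and max) from central finite differences of the raw touch
#' path, mean contact area, total drag duration, and windowed sensor
#' statistics anchored at the drag midpoint.
#'
#' @inheritParams tap_features
#' @param execution a drag `task_execution` (with its `spiral` attribute or
#'   an explicit `spec`).
#' @param spec the reference [spiral_spec()].
#' @return A `grip_features` named vector.
#' @export
drag_features <- function(execution, spec = attr(execution, "spiral"),
                          windows = event_windows_for(execution)) {
  if (execution$task != "drag") stopf("drag_features needs a drag execution")
  if (is.null(spec)) stopf("drag execution has no reference spiral")
  tch <- execution$touch
  if (nrow(tch) < 3) stopf("drag needs >= 3 touch samples for acceleration")
  trace_err <- mean(distance_to_spiral(spec, tch$x, tch$y))
  n <- nrow(tch)
  mid <- 2:(n - 1)
  vx <- (tch$x[mid + 1] - tch$x[mid - 1]) / (tch$t[mid + 1] - tch$t[mid - 1])
  vy <- (tch$y[mid + 1] - tch$y[mid - 1]) / (tch$t[mid + 1] - tch$t[mid - 1])
  speed <- sqrt(vx^2 + vy^2)
  tv <- tch$t[mid]
  if (length(tv) >= 3) {
    am <- 2:(length(tv) - 1)
    ax <- (vx[am + 1] - vx[am - 1]) / (tv[am + 1] - tv[am - 1])
    ay <- (vy[am + 1] - vy[am - 1]) / (tv[am + 1] - tv[am - 1])
    acc <- sqrt(ax^2 + ay^2)
  } else acc <- 0
  beh <- c(tracing_error_mm = trace_err,
           speed_mean_mm_s = mean(speed), speed_max_mm_s = max(speed),
           accel_mean_mm_s2 = mean(acc), accel_max_mm_s2 = max(acc),
           contact_area = mean(tch$contact_area),
           drag_duration_s = tch$t[n] - tch$t[1])
  sens <- rowMeans(vapply(windows, sensor_stats,
                          numeric(length(sensor_stat_names()))))
  finish_features(c(beh, sens), "drag")
}

#' Concatenate task-specific vectors into a unified vector
#'
#' @param tap,flick,drag `grip_features` vectors from the same session set.
#' @return A `grip_features` vector with task-prefixed names.
#' @export
assemble_unified <- function(tap, flick, drag) {
  parts <- list(tap = tap, flick = flick, drag = drag)
  vals <- unlist(lapply(names(parts), function(tk) {
    v <- as.numeric(parts[[tk]])
    names(v) <- paste(tk, names(parts[[tk]]), sep = "_")
    v
  }))
  finish_features(vals, "unified")
}

#' Extract feature matrices for all four scopes in one pass
#'
#' Computes the three per-task feature vectors once per session set and
#' assembles the tap, flick, drag, and unified matrices from them; the
#' result is identical to calling [extract_features()] four times at a
#' third of the cost.
#'
#' @inheritParams extract_features
#' @return Named list of four feature data frames
#'   (`tap`, `flick`, `drag`, `unified`).
#' @export
extract_features_all <- function(sets, cutoff = 20) {
  per_task <- lapply(sets, function(s) {
    tap <- tap_features(s$executions$tap,
                        event_windows_for(s$executions$tap, cutoff))
    flick <- flick_features(s$executions$flick,
                            event_windows_for(s$executions$flick, cutoff))
    drag <- drag_features(s$executions$drag,
                          windows = event_windows_for(s$executions$drag,
                                                      cutoff))
    list(tap = tap, flick = flick, drag = drag,
         unified = assemble_unified(tap, flick, drag))
  })
  build <- function(scope) {
    rows <- lapply(per_task, `[[`, scope)
    nm <- names(rows[[1]])
    vals <- do.call(rbind, lapply(rows, as.numeric))
    cols <- c(list(participant_id = vapply(sets, `[[`, "", "participant_id"),
                   day = vapply(sets, `[[`, 0L, "day"),
                   set_index = vapply(sets, `[[`, 0L, "set_index")),
              stats::setNames(lapply(seq_along(nm), function(j) vals[, j]),
                              nm),
              list(grip_kg = vapply(sets,
                                    function(s) s$grip$ground_truth, 0)))
    df <- fast_df(cols)
    attr(df, "task_scope") <- scope
    attr(df, "schema_hash") <- feature_schema_hash(c(nm, "grip_kg"))
    df
  }
  stats::setNames(lapply(c("tap", "flick", "drag", "unified"), build),
                  c("tap", "flick", "drag", "unified"))
}

#' Extract a feature matrix from a session collection
#'
#' Runs the preprocessing chain (gap interpolation, zero-phase low-pass at
#' `cutoff` Hz, event windows) and the per-task feature functions over every
#' session set, producing one row per set: the keys, the feature columns for
#' the requested scope, and the ground-truth `grip_kg` last.
#'
#' @param sets list of [session_set()] objects.
#' @param scope `"tap"`, `"flick"`, `"drag"`, or `"unified"`.
#' @param cutoff low-pass cutoff in Hz.
#' @return Feature data frame with a `task_scope` attribute.
#' @export
extract_features <- function(sets, scope = c("unified", "tap", "flick",
                                             "drag"), cutoff = 20) {
  scope <- match.arg(scope)
  rows <- lapply(sets, function(s) {
    fv <- switch(scope,
      tap = tap_features(s$executions$tap,
                         event_windows_for(s$executions$tap, cutoff)),
      flick = flick_features(s$executions$flick,
                             event_windows_for(s$executions$flick, cutoff)),
      drag = drag_features(s$executions$drag,
                           windows = event_windows_for(s$executions$drag,
                                                       cutoff)),
      unified = assemble_unified(
        tap_features(s$executions$tap,
                     event_windows_for(s$executions$tap, cutoff)),
        flick_features(s$executions$flick,
                       event_windows_for(s$executions$flick, cutoff)),
        drag_features(s$executions$drag,
                      windows = event_windows_for(s$executions$drag,
                                                  cutoff))))
    fv
  })
  nm <- names(rows[[1]])
  for (r in rows) if (!identical(names(r), nm))
    stopf("heterogeneous feature names across session sets")
  vals <- do.call(rbind, lapply(rows, as.numeric))
  cols <- c(list(participant_id = vapply(sets, `[[`, "", "participant_id"),
                 day = vapply(sets, `[[`, 0L, "day"),
                 set_index = vapply(sets, `[[`, 0L, "set_index")),
            stats::setNames(lapply(seq_along(nm), function(j) vals[, j]), nm),
            list(grip_kg = vapply(sets,
                                  function(s) s$grip$ground_truth, 0)))
  df <- fast_df(cols)
  attr(df, "task_scope") <- scope
  attr(df, "schema_hash") <- feature_schema_hash(c(nm, "grip_kg"))
  df
}
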