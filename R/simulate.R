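# Synthetic cohort generator. Emulates the study design (by default 21
# participants x 5 days x 10 consecutive sets x 3 tasks) with a latent grip
# model: population mean plus a between-user offset, a between-day offset,
# and a linear within-day fatigue decline across the 10 consecutive sets
# (each set follows a maximal dynamometer squeeze, which intentionally
# induces grip variability). Behavioral quantities are monotone functions of
# standardized grip mixed with user-idiosyncratic offsets; `coupling` sets
# the signal fraction, `1 - coupling` the noise fraction.

#' Cohort specification for the synthetic generator
#'
#' @param n_participants,n_days,sets_per_day study design counts
#'   (defaults 21, 5, 10).
#' @param grip_population_mean population mean grip, kg (default 30; most
#'   collected values concentrate between 25 and 35 kg).
#' @param user_sd between-user SD of latent grip, kg.
#' @param day_sd between-day within-user SD, kg.
#' @param fatigue_slope within-day decline, kg per consecutive set.
#' @param measurement_sd dynamometer reading noise SD, kg.
#' @param coupling signal fraction of the grip-to-behavior link in `[0, 1]`:
#'   0 means behavior is independent of grip, 1 means fully determined by it
#'   (up to per-event noise floors).
#' @param sensor_noise_sd white-noise scale added to every inertial channel
#'   (multiplies per-channel physical scales).
#' @param rng_seed master seed; per-participant substreams are derived from
#'   it so adding participants never perturbs existing ones.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 21, n_days = 5, sets_per_day = 10,
                        grip_population_mean = 30, user_sd = 5, day_sd = 1,
                        fatigue_slope = 0.3, measurement_sd = 0.5,
                        coupling = 0.7, sensor_noise_sd = 0.3,
                        rng_seed = 1L) {
  stopifnot(is_count(n_participants), is_count(n_days), is_count(sets_per_day),
            user_sd >= 0, day_sd >= 0, measurement_sd >= 0,
            sensor_noise_sd >= 0, coupling >= 0, coupling <= 1)
  if (grip_population_mean - fatigue_slope * (sets_per_day - 1) < 1)
    warnf("fatigue_slope %.2f kg/set drives mean grip below the 1 kg floor by set %d",
          fatigue_slope, sets_per_day)
  structure(list(n_participants = n_participants, n_days = n_days,
                 sets_per_day = sets_per_day,
                 grip_population_mean = grip_population_mean,
                 user_sd = user_sd, day_sd = day_sd,
                 fatigue_slope = fatigue_slope,
                 measurement_sd = measurement_sd, coupling = coupling,
                 sensor_noise_sd = sensor_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Derived per-participant seed; counter-based so cohorts are extendable.
participant_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 7919 * i) %% 2147483629 + 1)
}

# Smoothed unit-variance noise at 60 Hz (5-frame moving average, rescaled).
smooth_noise <- function(n) {
  w <- stats::rnorm(n + 4)
  v <- stats::filter(w, rep(1 / 5, 5), sides = 1)[5:(n + 4)]
  as.numeric(v) * sqrt(5)
}

# Gaussian bump of given center/width added around input events.
event_bump <- function(t, center, width = 0.05) exp(-((t - center) / width)^2)

# Synthesize the 9-channel sensor stream for one execution.
make_sensor_stream <- function(elapsed, anchors, jitter, noise_sd, base) {
  n <- ceiling(elapsed * 60) + 1
  t <- (seq_len(n) - 1) / 60
  scales <- c(rep(0.25, 3), rep(0.06, 3), rep(1.0, 3))  # m/s^2, rad/s, deg
  bump <- rowSums(vapply(anchors, function(a) event_bump(t, a), numeric(n)))
  cols <- c(list(t = t), lapply(seq_along(SENSOR_CHANNELS), function(k)
    base[k] + scales[k] *
      (jitter * (smooth_noise(n) + 1.5 * bump * stats::rnorm(n)) +
         noise_sd * stats::rnorm(n))))
  names(cols) <- c("t", SENSOR_CHANNELS)
  fast_df(cols)
}

stroke_rows <- function(t, x, y, area) {
  n <- length(t)
  phase <- c("down", rep("move", max(0, n - 2)), if (n > 1) "up")
  fast_df(list(t = t, x = x, y = y, phase = phase,
               contact_area = pmax(area + stats::rnorm(n, 0, 0.001), 0.001)))
}

bind_frames <- function(lst) {
  nm <- names(lst[[1]])
  out <- lapply(nm, function(cn) unlist(lapply(lst, `[[`, cn),
                                        use.names = FALSE))
  names(out) <- nm
  fast_df(out)
}

#' Generate a synthetic session cohort
#'
#' Latent grip for participant i, day d, set s is
#' `G = mu + u_i + v_id - fatigue_slope * (s - 1)`, truncated at 1 kg, with
#' `u_i ~ N(0, user_sd^2)` and `v_id ~ N(0, day_sd^2)`; the two dynamometer
#' readings add independent `N(0, measurement_sd^2)` noise. Touch and 60 Hz
#' inertial streams are synthesized consistently with the task layouts:
#' weaker grip lengthens touch durations, enlarges spatial and tracing
#' error, and increases device-motion jitter, with strength set by
#' `coupling`. Deterministic given `rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param screen a [screen_spec()].
#' @return List of [session_set()] objects.
#' @export
generate_cohort <- function(spec, screen = screen_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sp_right <- spiral_spec(screen = screen, chirality = "clockwise")
  sets <- vector("list", spec$n_participants * spec$n_days * spec$sets_per_day)
  idx <- 1L
  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("P%02d", i)
    sets_i <- local_seed(participant_seed(spec$rng_seed, i), {
      u_i <- stats::rnorm(1, 0, spec$user_sd)
      # user idiosyncrasy: stable behavioral/postural offsets. They scale
      # with coupling so that a coupling-0 cohort carries no stable user
      # signature at all: otherwise a pooled model could identify the user
      # from style alone and predict their mean grip, breaking the
      # no-signal null that coupling = 0 is meant to provide.
      cc <- spec$coupling
      delta <- stats::rnorm(1)
      off_dur <- stats::rnorm(1, 0, 0.02)
      off_err <- stats::rnorm(1, 0, 0.35)
      off_area <- stats::rnorm(1, 0, 0.008)
      base_sensor <- c(0, 3, 9.0, 0, 0, 0, 40, 5, 0) +
        cc * c(0, stats::rnorm(1, 0, 0.5), stats::rnorm(1, 0, 0.3), 0, 0, 0,
               stats::rnorm(1, 0, 8), stats::rnorm(1, 0, 4),
               stats::rnorm(1, 0, 10))
      out_i <- list()
      for (d in seq_len(spec$n_days)) {
        v_id <- stats::rnorm(1, 0, spec$day_sd)
        for (s in seq_len(spec$sets_per_day)) {
          G <- max(1, spec$grip_population_mean + u_i + v_id -
                        spec$fatigue_slope * (s - 1))
          r1 <- max(0, G + stats::rnorm(1, 0, spec$measurement_sd))
          r2 <- max(0, G + stats::rnorm(1, 0, spec$measurement_sd))
          z <- (G - spec$grip_population_mean) / 5
          # noise has an execution-level component (posture/arm state during
          # one task run, shared by its sub-events) plus per-event scatter;
          # the execution components are independent across the three tasks,
          # which is what a unified multi-task model can average over
          mk_drive <- function() {
            eta <- stats::rnorm(1)
            function() cc * (z + 0.35 * delta) +
              (1 - cc) * (0.6 * eta + 0.8 * stats::rnorm(1))
          }
          execs <- list(
            tap = make_tap_execution(mk_drive(), off_dur, off_err, off_area,
                                     base_sensor, spec$sensor_noise_sd,
                                     screen, cc),
            flick = make_flick_execution(mk_drive(), off_dur, off_area,
                                         base_sensor, spec$sensor_noise_sd,
                                         screen, cc),
            drag = make_drag_execution(mk_drive(), off_err, off_area,
                                       base_sensor, spec$sensor_noise_sd,
                                       sp_right, cc))
          out_i[[length(out_i) + 1L]] <-
            session_set(pid, d, s, grip_measurement(r1, r2), execs)
        }
      }
      out_i
    })
    for (s in sets_i) { sets[[idx]] <- s; idx <- idx + 1L }
  }
  sets
}

jitter_from <- function(b) clamp(0.9 - 0.35 * b, 0.15, 3)

make_tap_execution <- function(drive, off_dur, off_err, off_area,
                               base_sensor, noise_sd, screen, coupling) {
  targets <- sample_tap_targets(10, screen,
                                seed = sample.int(2^31 - 2, 1))
  t_cur <- 0.3
  sub <- list(); strokes <- list(); anchors <- numeric(10)
  b_mean <- 0
  for (k in 1:10) {
    b <- drive(); b_mean <- b_mean + b / 10
    elim <- clamp(0.55 - 0.12 * b + 0.05 * stats::rnorm(1), 0.15, 2)
    dur <- clamp(0.10 - 0.03 * b + coupling * off_dur +
                   0.01 * stats::rnorm(1), 0.02, 0.5)
    err <- clamp(2.0 - 0.6 * b + coupling * off_err +
                   0.3 * abs(stats::rnorm(1)), 0.05, 8)
    area <- clamp(0.045 + 0.010 * b + coupling * off_area +
                    0.003 * stats::rnorm(1), 0.005, 0.2)
    ang <- stats::runif(1, 0, 2 * pi)
    px <- clamp(targets$x[k] + err * cos(ang), 0, screen$width_mm)
    py <- clamp(targets$y[k] + err * sin(ang), 0, screen$height_mm)
    t_in <- t_cur + elim
    anchors[k] <- t_in
    sub[[k]] <- list(index = k, t_appear = t_cur, t_input = t_in,
                     target_x = targets$x[k], target_y = targets$y[k],
                     success = TRUE)
    strokes[[k]] <- stroke_rows(c(t_in, t_in + dur / 2, t_in + dur),
                                rep(px, 3), rep(py, 3), area)
    t_cur <- t_in + dur + 0.02
  }
  elapsed <- t_cur + 0.3
  task_execution("tap", bind_frames(sub), bind_frames(strokes),
                 make_sensor_stream(elapsed, anchors, jitter_from(b_mean),
                                    noise_sd, base_sensor), elapsed)
}

make_flick_execution <- function(drive, off_dur, off_area, base_sensor,
                                 noise_sd, screen, coupling) {
  t_cur <- 0.3
  sub <- list(); strokes <- list(); anchors <- numeric(10)
  b_mean <- 0
  margin <- 15
  for (k in 1:10) {
    b <- drive(); b_mean <- b_mean + b / 10
    bx <- stats::runif(1, margin, screen$width_mm - margin)
    by <- stats::runif(1, margin + 25, screen$height_mm - margin - 25)
    theta <- stats::runif(1, 0, 2 * pi)
    gx <- clamp(bx + 25 * cos(theta), 7.3, screen$width_mm - 7.3)
    gy <- clamp(by + 25 * sin(theta), 7.3, screen$height_mm - 7.3)
    elim <- clamp(0.60 - 0.12 * b + 0.05 * stats::rnorm(1), 0.2, 2)
    dur <- clamp(0.15 - 0.04 * b + coupling * off_dur +
                   0.02 * stats::rnorm(1), 0.05, 0.5)
    area <- clamp(0.040 + 0.010 * b + coupling * off_area +
                    0.003 * stats::rnorm(1), 0.005, 0.2)
    dir <- atan2(gy - by, gx - bx) + stats::rnorm(1, 0, 0.08)
    len <- clamp(12 + 2 * stats::rnorm(1), 5, 25)
    t_in <- t_cur + elim
    anchors[k] <- t_in
    n <- max(3, round(dur * 60))
    frac <- seq(0, 1, length.out = n)
    sx <- clamp(bx + frac * len * cos(dir), 0, screen$width_mm)
    sy <- clamp(by + frac * len * sin(dir), 0, screen$height_mm)
    sub[[k]] <- list(index = k, t_appear = t_cur, t_input = t_in,
                     target_x = gx, target_y = gy, success = TRUE)
    strokes[[k]] <- stroke_rows(t_in + frac * dur, sx, sy, area)
    t_cur <- t_in + dur + 0.05
  }
  elapsed <- t_cur + 0.3
  task_execution("flick", bind_frames(sub), bind_frames(strokes),
                 make_sensor_stream(elapsed, anchors, jitter_from(b_mean),
                                    noise_sd, base_sensor), elapsed)
}

make_drag_execution <- function(drive, off_err, off_area, base_sensor,
                                noise_sd, spiral, coupling) {
  b <- drive()
  dur <- clamp(3.4 - 0.8 * b + 0.4 * stats::rnorm(1), 1.5, 8)
  trace_sd <- clamp(0.8 - 0.25 * b + coupling * 0.3 * off_err, 0.08, 3)
  area <- clamp(0.045 + 0.010 * b + coupling * off_area +
                  0.003 * stats::rnorm(1), 0.005, 0.2)
  n <- max(10, round(dur * 60))
  s_grid <- seq(0, 1, length.out = n)
  pts <- spiral_point(spiral, s_grid)
  t0 <- 0.2
  tch <- stroke_rows(t0 + s_grid * dur,
                     pts[, 1] + stats::rnorm(n, 0, trace_sd),
                     pts[, 2] + stats::rnorm(n, 0, trace_sd), area)
  anchor <- t0 + dur / 2
  elapsed <- t0 + dur + 0.2
  sub <- data.frame(index = 1L, t_appear = 0, t_input = anchor,
                    target_x = spiral$center_x, target_y = spiral$center_y,
                    success = TRUE)
  task_execution("drag", sub, tch,
                 make_sensor_stream(elapsed, anchor, jitter_from(b),
                                    noise_sd, base_sensor), elapsed,
                 spiral = spiral)
}

#' Summary statistics of a cohort
#'
#' Record counts, per-participant grip mean and SD, and the pooled
#' within-day per-set trend slope (kg per set, by least squares of ground
#' truth on set index within participant-days).
#'
#' @param sets list of [session_set()] objects.
#' @return A list with `n_sets`, `per_participant`, and `set_slope`
#'   (`NA` with a flag when only one set exists).
#' @export
describe_cohort <- function(sets) {
  stopifnot(length(sets) > 0)
  df <- data.frame(
    participant_id = vapply(sets, `[[`, "", "participant_id"),
    day = vapply(sets, `[[`, 0L, "day"),
    set_index = vapply(sets, `[[`, 0L, "set_index"),
    grip = vapply(sets, function(s) s$grip$ground_truth, 0))
  per <- do.call(rbind, lapply(split(df, df$participant_id), function(g)
    data.frame(participant_id = g$participant_id[1], n = nrow(g),
               grip_mean = mean(g$grip), grip_sd = stats::sd(g$grip))))
  rownames(per) <- NULL
  if (length(unique(df$set_index)) < 2) {
    slope <- NA_real_; flag <- "undefined: fewer than 2 distinct sets"
  } else {
    fit <- stats::lm(grip ~ set_index + factor(paste(participant_id, day)),
                     data = df)
    slope <- unname(stats::coef(fit)["set_index"])
    flag <- NULL
  }
  list(n_sets = nrow(df), per_participant = per, set_slope = slope,
       slope_flag = flag)
}
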