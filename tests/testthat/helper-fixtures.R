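# Fixtures built in code: tiny cohorts, hand-made executions, and a fake
# feature frame for split/scheme tests where real streams are unnecessary.

tiny_cohort <- function(n_participants = 2, n_days = 2, sets_per_day = 2,
                        seed = 11, ...) {
  generate_cohort(cohort_spec(n_participants = n_participants,
                              n_days = n_days, sets_per_day = sets_per_day,
                              rng_seed = seed, ...))
}

# Uniform gap-free sensor stream with a constant value on every channel.
const_sensor <- function(n = 120, value = 1, fs = 60) {
  cols <- c(list(t = (seq_len(n) - 1) / fs),
            stats::setNames(rep(list(rep(value, n)), 9),
                            gripsense:::SENSOR_CHANNELS))
  as.data.frame(cols)
}

# Sensor stream where every channel equals the timestamp (linear ramp).
ramp_sensor <- function(n = 120, fs = 60) {
  s <- const_sensor(n, 0, fs)
  for (ch in gripsense:::SENSOR_CHANNELS) s[[ch]] <- s$t
  s
}

# Minimal hand-built tap execution: 10 sub-events, taps offset from the
# target centers by a known (dx, dy).
toy_tap_execution <- function(dx = 0, dy = 0, elim = 0.5, dur = 0.1,
                              area = 0.05) {
  tx <- seq(10, 60, length.out = 10)
  ty <- seq(20, 130, length.out = 10)
  t_app <- 0.3 + (seq_len(10) - 1) * (elim + dur + 0.02)
  t_in <- t_app + elim
  sub <- data.frame(index = 1:10, t_appear = t_app, t_input = t_in,
                    target_x = tx, target_y = ty, success = TRUE)
  touch <- do.call(rbind, lapply(1:10, function(k)
    data.frame(t = c(t_in[k], t_in[k] + dur), x = tx[k] + dx, y = ty[k] + dy,
               phase = c("down", "up"), contact_area = area)))
  elapsed <- max(touch$t) + 0.3
  task_execution("tap", sub, touch, const_sensor(ceiling(elapsed * 60) + 1),
                 elapsed)
}

# Flick execution with 10 identical straight strokes from (x0,y0) along
# (ux, uy) over `len` mm.
toy_flick_execution <- function(ux = 1, uy = 0, len = 10, dur = 0.2,
                                area = 0.04) {
  t_app <- 0.3 + (seq_len(10) - 1) * 0.8
  t_in <- t_app + 0.5
  sub <- data.frame(index = 1:10, t_appear = t_app, t_input = t_in,
                    target_x = 40, target_y = 80, success = TRUE)
  touch <- do.call(rbind, lapply(1:10, function(k) {
    frac <- seq(0, 1, length.out = 5)
    data.frame(t = t_in[k] + frac * dur, x = 30 + frac * len * ux,
               y = 60 + frac * len * uy,
               phase = c("down", "move", "move", "move", "up"),
               contact_area = area)
  }))
  elapsed <- max(touch$t) + 0.3
  task_execution("flick", sub, touch, const_sensor(ceiling(elapsed * 60) + 1),
                 elapsed)
}

# Drag execution whose trace follows the spiral centerline exactly (or a
# straight constant-velocity line when `straight = TRUE`).
toy_drag_execution <- function(spec = spiral_spec(), n = 120, dur = 2,
                               straight = FALSE, area = 0.05) {
  t <- 0.2 + seq(0, 1, length.out = n) * dur
  if (straight) {
    x <- seq(10, 60, length.out = n); y <- seq(20, 120, length.out = n)
  } else {
    p <- spiral_point(spec, seq(0, 1, length.out = n))
    x <- p[, 1]; y <- p[, 2]
  }
  touch <- data.frame(t = t, x = x, y = y,
                      phase = c("down", rep("move", n - 2), "up"),
                      contact_area = area)
  sub <- data.frame(index = 1L, t_appear = 0, t_input = 0.2 + dur / 2,
                    target_x = spec$center_x, target_y = spec$center_y,
                    success = TRUE)
  elapsed <- max(t) + 0.2
  task_execution("drag", sub, touch, const_sensor(ceiling(elapsed * 60) + 1),
                 elapsed, spiral = spec)
}

# Feature frame with the study's key structure but random feature columns;
# cheap stand-in for scheme/split tests.
fake_features <- function(n_participants = 5, n_days = 5, sets_per_day = 3,
                          p = 3, seed = 1) {
  set.seed(seed)
  keys <- expand.grid(set_index = seq_len(sets_per_day),
                      day = seq_len(n_days),
                      participant_id = sprintf("P%02d", seq_len(n_participants)),
                      stringsAsFactors = FALSE)
  n <- nrow(keys)
  df <- data.frame(participant_id = keys$participant_id, day = keys$day,
                   set_index = keys$set_index)
  for (j in seq_len(p)) df[[paste0("f", j)]] <- rnorm(n)
  df$grip_kg <- 30 + 3 * df$f1 + rnorm(n)
  df
}
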