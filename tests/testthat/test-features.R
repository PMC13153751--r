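# Behavioral and windowed-sensor feature extraction.

test_that("sensor_stats matches closed-form values on constant and ramp", {
  chans <- gripsense:::SENSOR_CHANNELS
  w <- structure(list(pre = matrix(2, 10, 9), during = setNames(rep(2, 9), chans),
                      post = matrix(2, 10, 9), pad_pre = 0, pad_post = 0),
                 class = "event_windows")
  s <- sensor_stats(w)
  expect_length(s, 99)
  expect_equal(unname(s["pre_sens_accel_x_range"]), 0)
  expect_equal(unname(s["post_sens_gyro_y_diffmean"]), 0)
  expect_equal(unname(s["pre_sens_orient_z_mean"]), 2)
  expect_equal(unname(s["sens_accel_z_during"]), 2)
  w$pre[, 1] <- 1:10
  s <- sensor_stats(w)
  expect_equal(unname(s[c("pre_sens_accel_x_max", "pre_sens_accel_x_min",
                          "pre_sens_accel_x_range", "pre_sens_accel_x_mean",
                          "pre_sens_accel_x_diffmean")]),
               c(10, 1, 9, 5.5, 1))
})

test_that("sensor_stats equals a naive recomputation on random windows", {
  set.seed(5)
  for (rep in 1:5) {
    w <- structure(list(pre = matrix(rnorm(90), 10, 9),
                        during = setNames(rnorm(9), gripsense:::SENSOR_CHANNELS),
                        post = matrix(rnorm(90), 10, 9),
                        pad_pre = 0, pad_post = 0), class = "event_windows")
    s <- sensor_stats(w)
    for (k in sample(9, 3)) {
      ch <- gripsense:::SENSOR_CHANNELS[k]
      v <- w$pre[, k]
      expect_equal(unname(s[paste0("pre_sens_", ch, "_max")]), max(v))
      expect_equal(unname(s[paste0("pre_sens_", ch, "_min")]), min(v))
      expect_equal(unname(s[paste0("pre_sens_", ch, "_range")]),
                   max(v) - min(v))
      expect_equal(unname(s[paste0("pre_sens_", ch, "_mean")]), mean(v))
      expect_equal(unname(s[paste0("pre_sens_", ch, "_diffmean")]),
                   mean(abs(diff(v))))
      u <- w$post[, k]
      expect_equal(unname(s[paste0("post_sens_", ch, "_mean")]), mean(u))
      expect_equal(unname(s[paste0("sens_", ch, "_during")]),
                   unname(w$during[k]))
    }
  }
})

test_that("tap features recover hand-computed per-sub-event aggregates", {
  ex0 <- toy_tap_execution(dx = 0, dy = 0)
  f0 <- tap_features(ex0)
  expect_equal(unname(f0["spatial_error_mm"]), 0)
  ex <- toy_tap_execution(dx = 3, dy = 4, elim = 0.5, dur = 0.1, area = 0.05)
  f <- tap_features(ex)
  expect_equal(unname(f["spatial_error_mm"]), 5)   # 3-4-5 offset
  expect_equal(unname(f["elim_time_s"]), 0.5)
  expect_equal(unname(f["touch_duration_s"]), 0.1)
  expect_equal(unname(f["contact_area"]), 0.05)
  expect_error(tap_features(toy_flick_execution()), "tap")
})

test_that("flick direction is the unit vector of the stroke", {
  f_right <- flick_features(toy_flick_execution(1, 0))
  expect_equal(unname(f_right[c("dir_x", "dir_y")]), c(1, 0))
  f_down <- flick_features(toy_flick_execution(0, 1))
  expect_equal(unname(f_down[c("dir_x", "dir_y")]), c(0, 1))
  set.seed(31)
  for (i in 1:10) {
    ang <- runif(1, 0, 2 * pi)
    f <- flick_features(toy_flick_execution(cos(ang), sin(ang)))
    expect_equal(unname(f["dir_x"]^2 + f["dir_y"]^2), 1, tolerance = 1e-9)
  }
})

test_that("zero-length flick strokes are excluded and counted", {
  ex <- toy_flick_execution(1, 0, len = 0)  # all strokes degenerate
  expect_error(flick_features(ex), "zero length")
})

test_that("drag features: on-centerline trace and constant-velocity line", {
  sp <- spiral_spec()
  f <- drag_features(toy_drag_execution(sp))
  expect_lt(unname(f["tracing_error_mm"]), 0.01)
  ex <- toy_drag_execution(sp, n = 100, dur = 2, straight = TRUE)
  f2 <- drag_features(ex)
  dist <- sqrt((60 - 10)^2 + (120 - 20)^2)
  expect_equal(unname(f2["speed_mean_mm_s"]), dist / 2, tolerance = 1e-6)
  expect_lt(unname(f2["accel_mean_mm_s2"]), 1e-6)
  expect_equal(unname(f2["drag_duration_s"]), 2)
})

test_that("drag tracing error matches the dense-sampling oracle composition", {
  sp <- spiral_spec()
  set.seed(12)
  ex <- toy_drag_execution(sp, n = 80)
  ex$touch$x <- ex$touch$x + rnorm(80, 0, 1)
  ex$touch$y <- ex$touch$y + rnorm(80, 0, 1)
  th <- seq(0, 2 * pi * sp$n_turns, length.out = 1e5)
  pp <- gripsense:::spiral_xy(sp, th)
  oracle <- mean(vapply(1:80, function(i)
    sqrt(min((pp[, 1] - ex$touch$x[i])^2 + (pp[, 2] - ex$touch$y[i])^2)),
    numeric(1)))
  f <- drag_features(ex)
  expect_equal(unname(f["tracing_error_mm"]), oracle, tolerance = 0.02)
})

test_that("unified assembly concatenates with task-prefixed names", {
  co <- tiny_cohort(1, 1, 1, seed = 4)
  s <- co[[1]]
  tap <- tap_features(s$executions$tap)
  flick <- flick_features(s$executions$flick)
  drag <- drag_features(s$executions$drag)
  u <- assemble_unified(tap, flick, drag)
  expect_length(u, length(tap) + length(flick) + length(drag))
  expect_true(all(startsWith(names(u)[seq_along(tap)], "tap_")))
  expect_equal(unname(u["flick_dir_x"]), unname(flick["dir_x"]))
})

test_that("features are translation invariant", {
  ex <- toy_tap_execution(dx = 3, dy = 4)
  shifted <- ex
  shifted$touch$x <- shifted$touch$x + 5
  shifted$touch$y <- shifted$touch$y + 2
  shifted$sub_events$target_x <- shifted$sub_events$target_x + 5
  shifted$sub_events$target_y <- shifted$sub_events$target_y + 2
  expect_equal(tap_features(shifted)["spatial_error_mm"],
               tap_features(ex)["spatial_error_mm"], tolerance = 1e-9)
  sp <- spiral_spec()
  ex2 <- toy_drag_execution(sp, n = 60)
  sp_shift <- sp; sp_shift$center_x <- sp$center_x + 4
  ex2_shift <- ex2
  ex2_shift$touch$x <- ex2$touch$x + 4
  attr(ex2_shift, "spiral") <- sp_shift
  expect_equal(drag_features(ex2_shift)[c("tracing_error_mm", "speed_mean_mm_s",
                                          "accel_mean_mm_s2")],
               drag_features(ex2)[c("tracing_error_mm", "speed_mean_mm_s",
                                    "accel_mean_mm_s2")], tolerance = 1e-6)
})

test_that("extraction is deterministic and finite on generated cohorts", {
  co <- tiny_cohort(2, 1, 2, seed = 19)
  f1 <- extract_features(co, "unified")
  f2 <- extract_features(co, "unified")
  expect_identical(f1, f2)
  expect_false(any(!is.finite(as.matrix(f1[, -(1:3)]))))
  all4 <- extract_features_all(co)
  expect_equal(all4$unified, f1)
  expect_equal(all4$tap, extract_features(co, "tap"))
})
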