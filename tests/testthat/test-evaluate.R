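# Error metrics, the three validation protocols, and raw NASA-TLX scoring.

test_that("metrics match closed-form examples", {
  m <- grip_metrics(c(10, 20), c(10, 20))
  expect_equal(unlist(m), c(mae = 0, mape = 0, r2 = 1))
  m2 <- grip_metrics(c(10, 20), c(11, 18))
  expect_equal(m2$mae, 1.5)
  expect_equal(m2$mape, 10)
  expect_error(grip_metrics(c(0, 10), c(1, 9)), "> 0")
  expect_warning(m3 <- grip_metrics(c(5, 5), c(4, 6)), "variance")
  expect_true(is.na(m3$r2))
})

test_that("metrics equal a naive loop recomputation on random vectors", {
  set.seed(3)
  true <- runif(200, 15, 45); pred <- true + rnorm(200, 0, 3)
  m <- grip_metrics(true, pred)
  mae <- 0; mape <- 0; ssr <- 0; sst <- 0
  for (i in 1:200) {
    mae <- mae + abs(true[i] - pred[i]) / 200
    mape <- mape + 100 * abs(true[i] - pred[i]) / true[i] / 200
    ssr <- ssr + (true[i] - pred[i])^2
    sst <- sst + (true[i] - mean(true))^2
  }
  expect_equal(m$mae, mae, tolerance = 1e-12)
  expect_equal(m$mape, mape, tolerance = 1e-12)
  expect_equal(m$r2, 1 - ssr / sst, tolerance = 1e-12)
})

test_that("MAPE is invariant under common positive rescaling", {
  set.seed(8)
  true <- runif(50, 20, 40); pred <- true + rnorm(50)
  expect_equal(grip_metrics(true, pred)$mape,
               grip_metrics(3 * true, 3 * pred)$mape, tolerance = 1e-12)
})

test_that("k-fold partitions 1050 rows into 5 folds of 210", {
  fold <- gripsense:::make_kfolds(1050, 5, seed = 2)
  expect_equal(as.integer(table(fold)), rep(210L, 5))
  expect_setequal(which(fold %in% 1:5), 1:1050)
  expect_error(gripsense:::make_kfolds(3, 5, 1), "folds")
})

test_that("k-fold evaluation reports per-fold metrics and beats no model", {
  df <- fake_features(6, 2, 4, p = 3, seed = 21)
  r <- eval_random_kfold(df, k = 5, seed = 7, algorithm = "knn")
  expect_s3_class(r, "grip_eval")
  expect_equal(nrow(r$per_unit), 5)
  expect_true(all(r$per_unit$mae >= 0))
  expect_true(all(r$per_unit$r2 <= 1))
  # f1 drives grip in the fake frame, so any learner beats the baseline
  expect_lt(r$summary$mape[["mean"]], r$summary$baseline_mape[["mean"]])
})

test_that("leave-one-user-out excludes the target participant entirely", {
  df <- fake_features(6, 2, 3, seed = 22)
  units <- gripsense:::louo_units(df)
  expect_length(units, 6)
  for (u in units) {
    expect_false(any(df$participant_id[u$train] == u$label))
    expect_true(all(df$participant_id[u$test] == u$label))
  }
  r <- eval_leave_one_user_out(df, algorithm = "knn")
  expect_equal(sort(r$per_unit$unit), sort(unique(df$participant_id)))
  expect_error(eval_leave_one_user_out(df[df$participant_id == "P01", ]),
               ">= 2")
})

test_that("calibration uses the first d days and tests the rest", {
  df <- fake_features(4, 5, 2, seed = 23)
  units <- gripsense:::calibration_units(df, 1)
  for (u in units) {
    own_train_days <- unique(df$day[u$train][df$participant_id[u$train] ==
                                               u$label])
    expect_equal(own_train_days, 1)
    expect_setequal(unique(df$day[u$test]), 2:5)
  }
  # d = 1 in the 5-day design: the target's remaining 4 days are tested
  expect_equal(length(units[[1]]$test), 4 * 2)
  expect_error(gripsense:::calibration_units(df, 5), "cannot calibrate")
})

test_that("zero calibration days reduces to leave-one-user-out", {
  df <- fake_features(4, 3, 2, seed = 24)
  a <- eval_few_day_calibration(df, 0, algorithm = "knn")
  b <- eval_leave_one_user_out(df, algorithm = "knn")
  expect_equal(a$per_unit, b$per_unit)
  expect_equal(a$calibration_days, 0L)
})

test_that("train and test rows never intersect in any scheme", {
  set.seed(30)
  for (rep in 1:10) {
    df <- fake_features(sample(3:7, 1), sample(2:5, 1), sample(1:3, 1),
                        seed = rep)
    ku <- gripsense:::kfold_units(df, sample(2:5, 1), seed = rep)
    lu <- gripsense:::louo_units(df)
    cu <- gripsense:::calibration_units(df, 1)
    for (u in c(ku, lu, cu)) {
      expect_length(intersect(u$train, u$test), 0)
      expect_true(all(c(u$train, u$test) %in% seq_len(nrow(df))))
    }
    # k-fold test folds partition all rows
    expect_setequal(unlist(lapply(ku, `[[`, "test")), seq_len(nrow(df)))
  }
})

test_that("raw TLX overall workload is the subscale mean to 2 decimals", {
  expect_equal(tlx_overall(c(1.89, 4.22, 5.11, 3.44, 1.78, 1.78)), 3.04)
  expect_equal(tlx_overall(rep(0, 6)), 0)
  set.seed(2)
  for (i in 1:20) {
    v <- runif(6, 0, 10)
    expect_equal(tlx_overall(v), round(sum(v) / 6, 2), tolerance = 1e-12)
  }
  expect_error(tlx_overall(c(1, 2, 3)), "exactly 6")
  expect_error(tlx_overall(c(1, 2, 3, 4, 5, 11)), "\\[0, 10\\]")
})

test_that("reports serialize to JSON keyed by scheme plus Markdown", {
  df <- fake_features(4, 3, 2, seed = 25)
  r1 <- eval_random_kfold(df, k = 3, seed = 1, algorithm = "knn")
  r2 <- eval_leave_one_user_out(df, algorithm = "knn")
  jp <- withr::local_tempfile(fileext = ".json")
  mp <- withr::local_tempfile(fileext = ".md")
  write_report(list(r1, r2), jp, mp)
  j <- jsonlite::fromJSON(jp)
  expect_setequal(names(j), c("random_kfold", "leave_one_user_out"))
  expect_equal(j$random_kfold$summary$mape$mean, r1$summary$mape[["mean"]])
  md <- readLines(mp)
  expect_match(md[1], "MAE")
  expect_length(md, 2 + 2)
})
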