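# Standardization, the four regressors, the k-NN oracle, grid search, and
# leakage guards.

test_that("standardized training columns have mean 0 and sd 1", {
  df <- fake_features(4, 2, 3, p = 5, seed = 2)
  m <- grip_fit(df, "knn")
  xs <- gripsense:::apply_scaler(m$scaler,
                                 as.matrix(df[, m$features]))
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_lt(max(abs(apply(xs, 2, sd) - 1)), 1e-9)
})

test_that("constant features get scale 1 with a warning", {
  df <- fake_features(3, 2, 2, p = 3, seed = 3)
  df$f2 <- 7
  expect_warning(m <- grip_fit(df, "knn"), "constant")
  expect_equal(unname(m$scaler$scale["f2"]), 1)
  expect_equal(unname(m$scaler$center["f2"]), 7)
})

test_that("all four algorithms are deterministic under random_state 42", {
  df <- fake_features(5, 2, 3, p = 4, seed = 7)
  probe <- fake_features(3, 1, 3, p = 4, seed = 8)
  for (a in c("svr_rbf", "random_forest", "gradient_boosting", "knn")) {
    p1 <- predict(grip_fit(df, a), probe)
    p2 <- predict(grip_fit(df, a), probe)
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
  }
})

test_that("a constant target is predicted exactly by every algorithm", {
  df <- fake_features(4, 2, 3, p = 3, seed = 4)
  df$grip_kg <- 25
  for (a in c("svr_rbf", "random_forest", "gradient_boosting", "knn")) {
    m <- grip_fit(df, a)
    expect_equal(predict(m, df), rep(25, nrow(df)), tolerance = 1e-6)
  }
})

test_that("k-NN matches a brute-force distance-weighted Manhattan oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(12:30, 1); p <- sample(2:5, 1)
    df <- data.frame(matrix(rnorm(n * p), n))
    names(df) <- paste0("f", seq_len(p))
    df$grip_kg <- runif(n, 20, 40)
    q <- data.frame(matrix(rnorm(5 * p), 5))
    names(q) <- paste0("f", seq_len(p))
    m <- grip_fit(df, "knn")
    mine <- predict(m, q)
    # independent oracle: standardize, loop over queries, weight by 1/d
    ctr <- colMeans(df[paste0("f", 1:p)])
    scl <- apply(df[paste0("f", 1:p)], 2, sd)
    oracle <- sapply(1:5, function(i) {
      d <- sapply(seq_len(n), function(j)
        sum(abs((as.numeric(q[i, ]) - ctr) / scl -
                  (as.numeric(df[j, 1:p]) - ctr) / scl)))
      o <- order(d)[1:9]
      if (any(d[o] == 0)) return(mean(df$grip_kg[o][d[o] == 0]))
      sum(df$grip_kg[o] / d[o]) / sum(1 / d[o])
    })
    expect_equal(mine, oracle, tolerance = 1e-9)
  }
})

test_that("k-NN handles exact-match queries by zero-distance convention", {
  df <- fake_features(3, 2, 2, p = 2, seed = 6)
  m <- grip_fit(df, "knn")
  pred <- predict(m, df[3, ])
  expect_equal(pred, df$grip_kg[3])
})

test_that("scaler absorbs affine rescaling of features (svr, knn)", {
  df <- fake_features(4, 2, 3, p = 3, seed = 10)
  probe <- fake_features(2, 1, 3, p = 3, seed = 11)
  for (a in c("svr_rbf", "knn")) {
    base <- predict(grip_fit(df, a), probe)
    df2 <- df; probe2 <- probe
    df2$f1 <- 10 * df2$f1 + 3
    probe2$f1 <- 10 * probe2$f1 + 3
    expect_equal(predict(grip_fit(df2, a), probe2), base, tolerance = 1e-9)
  }
})

test_that("held-out rows never influence the fit (leakage guard)", {
  df <- fake_features(5, 2, 3, p = 3, seed = 12)
  tr <- df[1:20, ]; te <- df[21:30, ]
  m <- grip_fit(tr, "svr_rbf")
  te_corrupt <- te
  te_corrupt$grip_kg <- te$grip_kg + 100
  expect_identical(predict(m, te), predict(m, te_corrupt))
})

test_that("schema mismatches are refused at predict time", {
  df <- fake_features(3, 2, 2, p = 3, seed = 13)
  m <- grip_fit(df, "knn")
  bad <- df; names(bad)[4] <- "other_feature"
  expect_error(predict(m, bad), "schema")
})

test_that("grid search minimizes CV MAPE deterministically", {
  df <- fake_features(6, 2, 3, p = 3, seed = 14)
  single <- grid_search("knn", list(k = 5), df, folds = 3, seed = 1)
  expect_equal(single$hyperparameters$k, 5)
  g <- grid_search("knn", list(k = c(3, 5, 9)), df, folds = 3, seed = 1)
  scores <- attr(g, "scores")
  expect_equal(g$hyperparameters$k, scores$k[which.min(scores$mean_mape)])
  g2 <- grid_search("knn", list(k = c(3, 5, 9)), df, folds = 3, seed = 1)
  expect_equal(g$hyperparameters, g2$hyperparameters)
})
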