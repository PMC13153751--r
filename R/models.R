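# Regression back ends. A single fitting interface wraps the four
# configured algorithms: random forest (200 trees, depth 20, sqrt-mtry),
# RBF-kernel support vector regression (C = 100, "scale" kernel width),
# gradient boosting (100 rounds, learning rate 0.1, depth 5), and
# distance-weighted k-nearest neighbors (k = 9, Manhattan metric).
# Features are z-score standardized with statistics learned from the
# training rows only.

ALGORITHMS <- c("svr_rbf", "random_forest", "gradient_boosting", "knn")

KEY_COLS <- c("participant_id", "day", "set_index")

#' Model configuration
#'
#' Builds an algorithm configuration with the study defaults; any
#' hyperparameter can be overridden through `...`.
#'
#' Defaults: `random_forest` — `n_estimators = 200`, `max_depth = 20`,
#' `mtry = "sqrt"`; `svr_rbf` — `C = 100`, `gamma = "scale"`,
#' `epsilon = 0.1`; `gradient_boosting` — `n_estimators = 100`,
#' `learning_rate = 0.1`, `max_depth = 5`; `knn` — `k = 9`,
#' distance weighting, Manhattan metric. `random_state` defaults to 42.
#'
#' @param algorithm one of `"svr_rbf"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"knn"`.
#' @param ... hyperparameter overrides.
#' @param random_state integer seed for the stochastic learners.
#' @return A `grip_config`.
#' @export
grip_config <- function(algorithm = ALGORITHMS, ..., random_state = 42L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    random_forest = list(n_estimators = 200L, max_depth = 20L, mtry = "sqrt"),
    svr_rbf = list(C = 100, gamma = "scale", epsilon = 0.1),
    gradient_boosting = list(n_estimators = 100L, learning_rate = 0.1,
                             max_depth = 5L),
    knn = list(k = 9L, weights = "distance", metric = "manhattan"))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 random_state = as.integer(random_state)),
            class = "grip_config")
}

split_xy <- function(data) {
  stopifnot(is.data.frame(data), "grip_kg" %in% names(data))
  feat <- setdiff(names(data), c(KEY_COLS, "grip_kg"))
  x <- as.matrix(data[, feat, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(data$grip_kg), features = feat)
}

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  const <- !is.finite(scale) | scale == 0
  if (any(const)) {
    warnf("constant feature(s) %s: scale set to 1",
          paste(colnames(x)[const], collapse = ", "))
    scale[const] <- 1
  }
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, x)
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")

#' Fit a grip-strength regression model
#'
#' Standardizes the feature columns (z-score; statistics from the training
#' rows only, constant columns get scale 1) and fits the configured
#' regressor on the standardized matrix. Key columns (`participant_id`,
#' `day`, `set_index`) are carried but never used as predictors; `grip_kg`
#' is the target. Deterministic for a fixed `random_state`.
#'
#' @param data feature data frame from [extract_features()].
#' @param algorithm algorithm name, used when `config` is not given.
#' @param config a [grip_config()].
#' @return A fitted `grip_model` with `print()`, `summary()`, `predict()`,
#'   `fitted()`, `residuals()`, and `plot()` methods.
#' @export
grip_fit <- function(data, algorithm = "svr_rbf",
                     config = grip_config(algorithm)) {
  stopifnot(inherits(config, "grip_config"))
  d <- split_xy(data)
  if (nrow(d$x) < 2) stopf("need at least 2 training rows")
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stopf("training data contain missing or non-finite values")
  scaler <- fit_scaler(d$x)
  xs <- apply_scaler(scaler, d$x)
  hp <- config$hyperparameters
  p <- ncol(xs)
  fit <- if (stats::sd(d$y) == 0) {
    # degenerate constant target: every regressor reduces to the constant
    list(constant = d$y[1])
  } else switch(config$algorithm,
    svr_rbf = {
      gamma <- if (identical(hp$gamma, "scale")) {
        v <- stats::var(as.vector(xs))
        if (!is.finite(v) || v == 0) v <- 1
        1 / (p * v)
      } else hp$gamma
      e1071::svm(x = xs, y = d$y, type = "eps-regression", kernel = "radial",
                 cost = hp$C, gamma = gamma, epsilon = hp$epsilon,
                 scale = FALSE)
    },
    random_forest = {
      mtry <- if (identical(hp$mtry, "sqrt")) max(1L, floor(sqrt(p)))
              else as.integer(hp$mtry)
      ranger::ranger(x = as.data.frame(xs), y = d$y,
                     num.trees = hp$n_estimators, max.depth = hp$max_depth,
                     mtry = mtry, seed = config$random_state,
                     num.threads = 1)
    },
    gradient_boosting = {
      local_seed(config$random_state, {
        dtrain <- xgboost::xgb.DMatrix(xs, label = d$y, nthread = 1)
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror",
                        eta = hp$learning_rate, max_depth = hp$max_depth,
                        tree_method = "exact", nthread = 1,
                        seed = config$random_state),
          data = dtrain, nrounds = hp$n_estimators, verbose = 0)
      })
    },
    knn = list(x = xs, y = d$y, k = hp$k, metric = hp$metric,
               weights = hp$weights))
  mdl <- structure(list(config = config, scaler = scaler, fit = fit,
                        features = d$features,
                        schema_hash = feature_schema_hash(c(d$features,
                                                            "grip_kg")),
                        train_y = d$y, n_train = nrow(d$x)),
                   class = "grip_model")
  mdl$train_fitted <- predict(mdl, data)
  mdl
}

# Distance-weighted k-NN regression; weight 1/d, with the standard
# convention that exact matches (distance 0) take the plain mean of the
# zero-distance neighbors' targets.
knn_predict <- function(fit, xs) {
  apply(xs, 1, function(q) {
    d <- if (fit$metric == "manhattan")
      colSums(abs(t(fit$x) - q))
    else sqrt(colSums((t(fit$x) - q)^2))
    ord <- order(d)[seq_len(min(fit$k, length(d)))]
    dk <- d[ord]
    if (identical(fit$weights, "distance")) {
      if (any(dk == 0)) return(mean(fit$y[ord][dk == 0]))
      w <- 1 / dk
      sum(w * fit$y[ord]) / sum(w)
    } else mean(fit$y[ord])
  })
}

#' Predict grip strength from a fitted model
#'
#' @param object a `grip_model`.
#' @param newdata feature data frame with the same feature schema the model
#'   was trained on (key columns optional).
#' @param ... unused.
#' @return Numeric vector of grip estimates in kg.
#' @export
predict.grip_model <- function(object, newdata, ...) {
  feat <- object$features
  miss <- setdiff(feat, names(newdata))
  if (length(miss))
    stopf("feature schema mismatch: newdata lacks %d column(s) (e.g. %s)",
          length(miss), miss[1])
  x <- as.matrix(newdata[, feat, drop = FALSE])
  storage.mode(x) <- "double"
  xs <- apply_scaler(object$scaler, x)
  if (!is.null(object$fit$constant))
    return(rep(object$fit$constant, nrow(xs)))
  out <- switch(object$config$algorithm,
    svr_rbf = as.numeric(stats::predict(object$fit, xs)),
    random_forest = stats::predict(object$fit, as.data.frame(xs),
                                   num.threads = 1)$predictions,
    gradient_boosting = as.numeric(stats::predict(
      object$fit, xgboost::xgb.DMatrix(xs, nthread = 1))),
    knn = knn_predict(object$fit, xs))
  unname(out)
}

#' @export
print.grip_model <- function(x, ...) {
  hp <- x$config$hyperparameters
  cat(sprintf("<grip_model> %s (%s)\n", x$config$algorithm,
              paste(names(hp), vapply(hp, format, ""), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  trained on %d rows x %d features (schema %s)\n",
              x$n_train, length(x$features), x$schema_hash))
  invisible(x)
}

#' @export
summary.grip_model <- function(object, ...) {
  res <- residuals(object)
  cat(sprintf("Grip model: %s, %d rows, %d features\n",
              object$config$algorithm, object$n_train,
              length(object$features)))
  cat(sprintf("Training residuals: MAE %.3f kg, RMSE %.3f kg\n",
              mean(abs(res)), sqrt(mean(res^2))))
  invisible(object)
}

#' @export
fitted.grip_model <- function(object, ...) object$train_fitted

#' @export
residuals.grip_model <- function(object, ...)
  object$train_y - object$train_fitted

#' Plot observed versus predicted grip
#'
#' @param x a `grip_model`.
#' @param newdata feature data frame with a `grip_kg` column.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grip_model <- function(x, newdata, ...) {
  pred <- predict(x, newdata)
  graphics::plot(newdata$grip_kg, pred, xlab = "measured grip (kg)",
                 ylab = "estimated grip (kg)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Grid search over hyperparameters
#'
#' Exhaustive search minimizing mean cross-validated MAPE. Candidates are
#' enumerated in the order given by `grid` (first parameter varying
#' slowest); ties keep the earliest candidate, so selection is
#' deterministic.
#'
#' @param algorithm algorithm name.
#' @param grid named list of value vectors.
#' @param data feature data frame.
#' @param folds number of CV folds.
#' @param seed shuffling seed for the folds.
#' @return The winning [grip_config()], with a `scores` attribute holding
#'   the per-candidate mean MAPE table.
#' @export
grid_search <- function(algorithm, grid, data, folds = 5, seed = 42) {
  stopifnot(length(grid) > 0, folds >= 2)
  cand <- expand.grid(rev(grid), stringsAsFactors = FALSE)[, rev(seq_along(grid)),
                                                           drop = FALSE]
  names(cand) <- names(grid)
  fold_id <- make_kfolds(nrow(data), folds, seed)
  scores <- rep(NA_real_, nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    cfg <- do.call(grip_config, c(list(algorithm = algorithm),
                                  as.list(cand[ci, , drop = FALSE])))
    mapes <- tryCatch(
      vapply(seq_len(folds), function(f) {
        tr <- data[fold_id != f, , drop = FALSE]
        te <- data[fold_id == f, , drop = FALSE]
        m <- grip_fit(tr, config = cfg)
        grip_metrics(te$grip_kg, predict(m, te))$mape
      }, numeric(1)),
      error = function(e) {
        warnf("candidate %d failed: %s", ci, conditionMessage(e))
        NULL
      })
    if (!is.null(mapes)) scores[ci] <- mean(mapes)
  }
  if (all(is.na(scores))) stopf("every grid candidate failed to fit")
  best <- which.min(scores)  # first minimum wins ties
  out <- do.call(grip_config, c(list(algorithm = algorithm),
                                as.list(cand[best, , drop = FALSE])))
  attr(out, "scores") <- cbind(cand, mean_mape = scores)
  out
}
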