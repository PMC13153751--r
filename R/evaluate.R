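# Validation protocols and error metrics. Three schemes mirror the study:
# a 5-fold random split of all rows, leave-one-user-out (every row of one
# participant held out), and few-day calibration (other participants' rows
# plus the target's first d days in training, their remaining days in
# test). A mean-predictor baseline is always computed on the same splits,
# since relative improvement over it is the testable surface on synthetic
# data.

#' Grip estimation error metrics
#'
#' MAE (kg), MAPE (%), and the coefficient of determination:
#' `MAE = mean|true - pred|`, `MAPE = 100 * mean(|true - pred| / true)`,
#' `R^2 = 1 - sum((true - pred)^2) / sum((true - mean(true))^2)`.
#'
#' @param true,pred equal-length vectors of measured and estimated grip, kg.
#'   All `true` values must be positive (MAPE is undefined otherwise).
#' @return List with `mae`, `mape`, `r2` (`r2` is `NA` with a warning when
#'   `true` has zero variance).
#' @export
grip_metrics <- function(true, pred) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  if (any(true <= 0)) stopf("MAPE undefined: true grip values must be > 0")
  mae <- mean(abs(true - pred))
  mape <- 100 * mean(abs(true - pred) / true)
  sst <- sum((true - mean(true))^2)
  if (sst == 0) {
    warnf("zero variance in true values: R^2 undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum((true - pred)^2) / sst
  list(mae = mae, mape = mape, r2 = r2)
}

# Shuffle rows with `seed` and deal them into k near-equal folds.
make_kfolds <- function(n, k, seed) {
  if (k > n) stopf("cannot make %d folds from %d rows", k, n)
  local_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
    fold
  })
}

new_eval <- function(scheme, per_unit, algorithm, n, extra = list()) {
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  structure(c(list(scheme = scheme, algorithm = algorithm, n = n,
                   per_unit = per_unit,
                   summary = list(mae = agg(per_unit$mae),
                                  mape = agg(per_unit$mape),
                                  r2 = agg(per_unit$r2),
                                  baseline_mae = agg(per_unit$baseline_mae),
                                  baseline_mape = agg(per_unit$baseline_mape))),
              extra),
            class = "grip_eval")
}

eval_units <- function(data, units, scheme, config) {
  per <- do.call(rbind, lapply(units, function(u) {
    tr <- data[u$train, , drop = FALSE]
    te <- data[u$test, , drop = FALSE]
    m <- grip_fit(tr, config = config)
    met <- grip_metrics(te$grip_kg, predict(m, te))
    base <- grip_metrics(te$grip_kg, rep(mean(tr$grip_kg), nrow(te)))
    data.frame(unit = u$label, n_test = nrow(te), mae = met$mae,
               mape = met$mape, r2 = met$r2, baseline_mae = base$mae,
               baseline_mape = base$mape)
  }))
  rownames(per) <- NULL
  new_eval(scheme, per, config$algorithm, nrow(data))
}

# Unit builders: each returns a list of folds with train/test row indices.
kfold_units <- function(data, k, seed) {
  fold <- make_kfolds(nrow(data), k, seed)
  lapply(seq_len(k), function(f)
    list(label = sprintf("fold%d", f), train = which(fold != f),
         test = which(fold == f)))
}

louo_units <- function(data) {
  ids <- unique(data$participant_id)
  if (length(ids) < 2) stopf("leave-one-user-out needs >= 2 participants")
  lapply(ids, function(id)
    list(label = id, train = which(data$participant_id != id),
         test = which(data$participant_id == id)))
}

calibration_units <- function(data, d, targets = NULL) {
  ids <- targets %||% unique(data$participant_id)
  lapply(ids, function(id) {
    days <- sort(unique(data$day[data$participant_id == id]))
    if (length(days) <= d)
      stopf("participant %s has %d day(s); cannot calibrate on %d",
            id, length(days), d)
    cal <- days[seq_len(d)]
    list(label = id,
         train = which(data$participant_id != id |
                         (data$participant_id == id & data$day %in% cal)),
         test = which(data$participant_id == id & !(data$day %in% cal)))
  })
}

#' Random k-fold cross-validation
#'
#' Rows are shuffled with `seed` and partitioned into `k` near-equal folds;
#' each fold is predicted by a model fitted on the remaining rows. Metrics
#' are computed per fold and summarized as mean (SD) across folds.
#'
#' @param data feature data frame from [extract_features()].
#' @param k number of folds (study default 5).
#' @param seed shuffling seed.
#' @param algorithm,config model choice as in [grip_fit()].
#' @return A `grip_eval` report.
#' @export
eval_random_kfold <- function(data, k = 5, seed = 42, algorithm = "svr_rbf",
                              config = grip_config(algorithm)) {
  out <- eval_units(data, kfold_units(data, k, seed), "random_kfold", config)
  out$seed <- seed
  out
}

#' Leave-one-user-out validation
#'
#' One fold per participant: every row of that participant is held out and
#' predicted by a model trained on all other participants. Measures
#' cross-person generalization; no target-user data enters training.
#'
#' @inheritParams eval_random_kfold
#' @return A `grip_eval` report with one unit per participant.
#' @export
eval_leave_one_user_out <- function(data, algorithm = "svr_rbf",
                                    config = grip_config(algorithm)) {
  eval_units(data, louo_units(data), "leave_one_user_out", config)
}

#' Few-day personal calibration
#'
#' For each target participant, training pools every other participant's
#' rows plus the target's chronologically first `d` days; testing uses the
#' target's remaining days. `d = 0` is exactly leave-one-user-out.
#'
#' @inheritParams eval_random_kfold
#' @param d number of calibration days (0..4 in the 5-day design).
#' @param targets participants to evaluate (default: all with more than
#'   `d` distinct days).
#' @return A `grip_eval` report with one unit per target participant.
#' @export
eval_few_day_calibration <- function(data, d, algorithm = "svr_rbf",
                                     config = grip_config(algorithm),
                                     targets = NULL) {
  stopifnot(d >= 0, d == round(d))
  if (d == 0) {
    out <- eval_leave_one_user_out(data, config = config)
    out$scheme <- "few_day_calibration"
    out$calibration_days <- 0L
    return(out)
  }
  out <- eval_units(data, calibration_units(data, d, targets),
                    "few_day_calibration", config)
  out$calibration_days <- as.integer(d)
  out
}

#' @export
print.grip_eval <- function(x, ...) {
  s <- x$summary
  hdr <- x$scheme
  if (!is.null(x$calibration_days))
    hdr <- sprintf("%s (d = %d)", hdr, x$calibration_days)
  cat(sprintf("<grip_eval> %s, %s, %d rows, %d folds\n", hdr, x$algorithm,
              x$n, nrow(x$per_unit)))
  cat(sprintf("  MAE  %.2f (SD %.2f) kg   [baseline %.2f]\n",
              s$mae["mean"], s$mae["sd"], s$baseline_mae["mean"]))
  cat(sprintf("  MAPE %.2f (SD %.2f) %%    [baseline %.2f]\n",
              s$mape["mean"], s$mape["sd"], s$baseline_mape["mean"]))
  cat(sprintf("  R^2  %.3f (SD %.3f)\n", s$r2["mean"], s$r2["sd"]))
  invisible(x)
}

eval_to_list <- function(r) {
  list(scheme = r$scheme, algorithm = r$algorithm, n = r$n,
       calibration_days = r$calibration_days,
       summary = lapply(r$summary, function(v) as.list(v)),
       per_unit = r$per_unit)
}

#' Write evaluation reports as JSON and Markdown
#'
#' JSON is keyed by validation scheme (schemes occurring more than once,
#' e.g. several calibration depths, become arrays); the Markdown rendering
#' is one table row per report.
#'
#' @param reports a `grip_eval` or list of them.
#' @param json_path,md_path output files (`NULL` to skip one format).
#' @return `json_path`, invisibly.
#' @export
write_report <- function(reports, json_path, md_path = NULL) {
  if (inherits(reports, "grip_eval")) reports <- list(reports)
  by_scheme <- split(lapply(reports, eval_to_list),
                     vapply(reports, `[[`, "", "scheme"))
  by_scheme <- lapply(by_scheme, function(g) if (length(g) == 1) g[[1]] else g)
  jsonlite::write_json(by_scheme, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  if (!is.null(md_path)) {
    lines <- c("| scheme | algorithm | d | MAE kg (SD) | MAPE % (SD) | R2 (SD) |",
               "|---|---|---|---|---|---|")
    for (r in reports) {
      s <- r$summary
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %.2f (%.2f) | %.2f (%.2f) | %.3f (%.3f) |",
        r$scheme, r$algorithm,
        if (is.null(r$calibration_days)) "" else r$calibration_days,
        s$mae["mean"], s$mae["sd"], s$mape["mean"], s$mape["sd"],
        s$r2["mean"], s$r2["sd"]))
    }
    writeLines(lines, md_path)
  }
  invisible(json_path)
}

#' Raw NASA-TLX overall workload
#'
#' The unweighted (raw) Task Load Index: participants rate six subscales
#' (mental, physical, and temporal demand, performance, effort,
#' frustration) on an 11-point 0 (low) to 10 (high) scale; the overall
#' workload is their arithmetic mean, reported to two decimals.
#'
#' @param subscales numeric vector of exactly 6 subscale scores in `[0, 10]`.
#' @return Overall workload score, rounded to 2 decimals.
#' @export
tlx_overall <- function(subscales) {
  if (length(subscales) != 6)
    stopf("raw TLX needs exactly 6 subscale scores, got %d", length(subscales))
  if (any(!is.finite(subscales)) || any(subscales < 0) || any(subscales > 10))
    stopf("TLX subscale scores must lie in [0, 10]")
  round(mean(subscales), 2)
}
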