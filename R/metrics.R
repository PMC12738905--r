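#' Evaluate a fitted growth model on held-out data
#'
#' Computes MAE, MSE, RMSE and R-squared per output with the standard
#' definitions (`R2 = 1 - SS_res / SS_tot`), plus the comprehensive
#' R-squared — the weighted average of the per-output R-squared values
#' used to rank candidate models (equal weights by default, mirroring the
#' near-equal comprehensive weights of hypocotyl length and stem
#' diameter).
#'
#' @param object A `growth_fit`.
#' @param test Held-out tibble with feature and target columns.
#' @param r2_weights Length-2 non-negative weights (hypocotyl, stem)
#'   summing to 1 for the comprehensive R-squared.
#' @return An object of class `"growth_eval"`: list with `metrics` (one
#'   row per output: `target`, `mae`, `mse`, `rmse`, `r2`),
#'   `comprehensive_r2`, `train_time_s`, `predict_time_s`, `n_test` and
#'   `algorithm`.
#' @export
evaluate_growth_model <- function(object, test, r2_weights = c(0.5, 0.5)) {
  test <- as_tibble(test)
  if (nrow(test) == 0) abort("test set is empty")
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(object, test)
  predict_time <- proc.time()[["elapsed"]] - t0

  metrics <- purrr::map_dfr(object$targets, function(target) {
    obs <- test[[target]]
    est <- pred[[target]]
    regression_metrics(obs, est) %>% mutate(target = target, .before = 1)
  })
  comp <- comprehensive_r2(metrics$r2[1], metrics$r2[2], r2_weights)
  structure(
    list(metrics = metrics, comprehensive_r2 = comp,
         train_time_s = object$train_time_s, predict_time_s = predict_time,
         n_test = nrow(test), algorithm = object$spec$algorithm),
    class = "growth_eval"
  )
}

#' Standard regression metrics
#'
#' @param obs,est Observed and predicted numeric vectors.
#' @return One-row tibble with `mae`, `mse`, `rmse`, `r2`. `r2` is `NaN`
#'   (with a warning) when the observations have zero variance.
#' @export
regression_metrics <- function(obs, est) {
  if (length(obs) != length(est)) abort("obs and est lengths differ")
  resid <- obs - est
  mae <- mean(abs(resid))
  mse <- mean(resid^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warn("zero-variance observations: R-squared undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(resid^2) / ss_tot
  }
  tibble(mae = mae, mse = mse, rmse = sqrt(mse), r2 = r2)
}

#' Weighted comprehensive R-squared
#'
#' The comprehensive R-squared of a two-output growth model is the
#' weighted average of the per-output R-squared values, with weights
#' taken from the comprehensive indicator weighting (hypocotyl length and
#' stem diameter dominate the comprehensive weights and are nearly equal,
#' so equal weights are the default).
#'
#' @param r2_hypocotyl,r2_stem Per-output R-squared values.
#' @param weights Length-2 non-negative weights summing to 1.
#' @return Single numeric value.
#' @examples
#' comprehensive_r2(0.9305, 0.9363)  # 0.9334
#' @export
comprehensive_r2 <- function(r2_hypocotyl, r2_stem, weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be two non-negative values summing to 1")
  }
  weights[1] * r2_hypocotyl + weights[2] * r2_stem
}

#' Relative improvement of an error metric
#'
#' Percentage by which an error metric improved between two model
#' versions: `100 * (before - after) / before`.
#'
#' @param before,after Metric values; `before` must be positive.
#' @return Improvement in percent (positive = `after` is better).
#' @examples
#' relative_improvement(3.4375, 3.2628)   # 5.08 % MAE improvement
#' relative_improvement(24.5805, 20.7465) # 15.6 % MSE improvement
#' @export
relative_improvement <- function(before, after) {
  if (!is.finite(before) || before <= 0) {
    abort("'before' must be a positive finite metric value")
  }
  100 * (before - after) / before
}

#' @export
print.growth_eval <- function(x, ...) {
  cat("<growth_eval> ", x$algorithm, " on ", x$n_test, " records; ",
      "comprehensive R2 = ", format(round(x$comprehensive_r2, 4)), "\n",
      sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
#' @method tidy growth_eval
tidy.growth_eval <- function(x, ...) x$metrics

#' @export
#' @method glance growth_eval
glance.growth_eval <- function(x, ...) {
  wide <- x$metrics %>%
    tidyr::pivot_wider(names_from = "target",
                       values_from = c("mae", "mse", "rmse", "r2"))
  bind_cols(
    tibble(algorithm = x$algorithm, comprehensive_r2 = x$comprehensive_r2),
    wide,
    tibble(train_time_s = x$train_time_s, predict_time_s = x$predict_time_s,
           n_test = x$n_test)
  )
}

#' Compare candidate growth models on one dataset
#'
#' Applies the same time-series split to the dataset, fits every
#' specification on the training days and evaluates on the held-out
#' days, ranking by comprehensive R-squared. Wall-clock training and
#' prediction times are reported for context (they are
#' hardware-dependent and not a model-quality metric).
#'
#' @param data Growth dataset.
#' @param specs List of [model_spec()] objects (at least 2 for a
#'   meaningful ranking; 1 is allowed).
#' @param train_fraction Passed to [time_series_split()].
#' @param augment Augment the training set first (see
#'   [augment_training()])?
#' @param r2_weights Passed to [evaluate_growth_model()].
#' @return Tibble with one row per spec, columns from
#'   `glance.growth_eval()` plus `rank`, ordered best-first.
#' @export
compare_models <- function(data, specs, train_fraction = 0.8,
                           augment = FALSE, r2_weights = c(0.5, 0.5)) {
  if (!is.list(specs) || length(specs) < 1) {
    abort("specs must be a non-empty list of model_spec objects")
  }
  split <- time_series_split(data, train_fraction)
  train <- if (augment) augment_training(split$train) else split$train
  rows <- purrr::map_dfr(specs, function(spec) {
    fit <- fit_growth_model(train, spec)
    glance(evaluate_growth_model(fit, split$test, r2_weights))
  })
  rows %>%
    arrange(dplyr::desc(.data$comprehensive_r2)) %>%
    mutate(rank = row_number())
}
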