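#' Model specification for forward growth prediction
#'
#' Describes one of the supported regressors and its hyperparameters.
#' Defaults follow common practice for each family: ridge penalty 1.0;
#' random forest with 100 trees; gradient boosting with 200 rounds,
#' learning rate 0.1, maximum depth 6, row subsample 0.8. All stochastic
#' algorithms run under `seed` (default 42).
#'
#' @param algorithm One of `"linear"`, `"ridge"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param ... Named hyperparameter overrides (`penalty` for ridge;
#'   `num_trees` for the forest; `nrounds`, `learning_rate`, `max_depth`,
#'   `subsample` for boosting).
#' @param seed Integer seed.
#' @return A list of class `"model_spec"`.
#' @examples
#' model_spec("gradient_boosting")
#' model_spec("ridge", penalty = 0.5)
#' @export
model_spec <- function(algorithm = c("gradient_boosting", "linear", "ridge",
                                     "random_forest"),
                       ..., seed = 42) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    linear = list(),
    ridge = list(penalty = 1.0),
    random_forest = list(num_trees = 100),
    gradient_boosting = list(nrounds = 200, learning_rate = 0.1,
                             max_depth = 6, subsample = 0.8)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown hyperparameter(s) for ", algorithm, ": ",
                 paste(unknown, collapse = ", ")))
  }
  defaults[names(dots)] <- dots
  structure(list(algorithm = algorithm, hyperparameters = defaults,
                 seed = seed),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$algorithm, " (seed ", x$seed, ")\n", sep = "")
  if (length(x$hyperparameters) > 0) {
    str(x$hyperparameters, give.attr = FALSE, no.list = TRUE)
  }
  invisible(x)
}

growth_features <- c("red_umol", "blue_umol", "photoperiod_h", "day")
growth_targets <- c("hypocotyl_mm", "stem_mm")

#' Fit a forward growth model
#'
#' Fits a two-output regressor predicting hypocotyl length and stem
#' diameter (mm) from the light recipe (red, blue, photoperiod) and the
#' day after emergence. Each output gets its own fitted regressor of the
#' requested family; predictions come back as a two-column tibble.
#' Fitting is deterministic given the spec's seed.
#'
#' @param data Training tibble containing the feature columns `red_umol`,
#'   `blue_umol`, `photoperiod_h`, `day` and target columns
#'   `hypocotyl_mm`, `stem_mm`.
#' @param spec A [model_spec()].
#' @return An object of class `"growth_fit"`.
#' @examples
#' d <- generate_design_dataset(n_per_treatment = 1, seed = 1)
#' fit <- fit_growth_model(d, model_spec("linear"))
#' predict(fit, d[1:3, ])
#' @export
fit_growth_model <- function(data, spec = model_spec()) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("training data is empty")
  missing <- setdiff(c(growth_features, growth_targets), names(data))
  if (length(missing) > 0) {
    abort(paste0("training data lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, growth_features])
  if (any(!is.finite(X))) abort("features must be finite")

  t0 <- proc.time()[["elapsed"]]
  fits <- lapply(growth_targets, function(target) {
    y <- data[[target]]
    if (any(!is.finite(y))) abort(paste0("target ", target, " must be finite"))
    fit_single_output(spec, X, y)
  })
  names(fits) <- growth_targets
  train_time <- proc.time()[["elapsed"]] - t0

  structure(
    list(spec = spec, fits = fits, features = growth_features,
         targets = growth_targets, n_train = nrow(data),
         train_time_s = train_time),
    class = "growth_fit"
  )
}

fit_single_output <- function(spec, X, y) {
  hp <- spec$hyperparameters
  if (sd(y) == 0 && spec$algorithm %in% c("linear", "ridge")) {
    return(list(type = "constant", value = y[1]))
  }
  switch(spec$algorithm,
    linear = {
      df <- as.data.frame(X); df$.y <- y
      list(type = "lm", model = lm(.y ~ ., data = df))
    },
    ridge = {
      # closed-form ridge with unpenalized intercept on raw features
      Xc <- cbind(`(Intercept)` = 1, X)
      P <- diag(c(0, rep(hp$penalty, ncol(X))))
      beta <- solve(crossprod(Xc) + P, crossprod(Xc, y))
      list(type = "ridge", beta = as.numeric(beta))
    },
    random_forest = {
      df <- as.data.frame(X); df$.y <- y
      list(type = "ranger",
           model = ranger::ranger(.y ~ ., data = df,
                                  num.trees = hp$num_trees,
                                  seed = spec$seed))
    },
    gradient_boosting = {
      set.seed(spec$seed)
      dm <- xgboost::xgb.DMatrix(X, label = y)
      booster <- xgboost::xgb.train(
        params = list(eta = hp$learning_rate, max_depth = hp$max_depth,
                      subsample = hp$subsample, objective = "reg:squarederror",
                      nthread = 1),
        data = dm, nrounds = hp$nrounds, verbose = 0
      )
      list(type = "xgb", model = booster)
    }
  )
}

predict_single_output <- function(fit, xmat) {
  switch(fit$type,
    constant = rep(fit$value, nrow(xmat)),
    lm = as.numeric(predict(fit$model, as.data.frame(xmat))),
    ridge = as.numeric(cbind(1, xmat) %*% fit$beta),
    ranger = predict(fit$model, as.data.frame(xmat))$predictions,
    xgb = as.numeric(predict(fit$model, xmat))
  )
}

#' Predict seedling morphology from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param newdata Tibble (or matrix) with the feature columns `red_umol`,
#'   `blue_umol`, `photoperiod_h`, `day`.
#' @param ... Unused.
#' @return Tibble with predicted `hypocotyl_mm` and `stem_mm`.
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    X <- newdata
    colnames(X) <- object$features
  } else {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing) > 0) {
      abort(paste0("newdata lacks feature column(s): ",
                   paste(missing, collapse = ", ")))
    }
    X <- as.matrix(as_tibble(newdata)[, object$features])
  }
  out <- lapply(object$fits, predict_single_output, xmat = X)
  as_tibble(out)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$spec$algorithm, ", n_train = ", x$n_train,
      ", train time ", format(round(x$train_time_s, 3)), " s\n", sep = "")
  invisible(x)
}
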