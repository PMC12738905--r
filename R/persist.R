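#' Save / load a fitted growth model
#'
#' Persists a `growth_fit` as a self-describing archive: the model
#' specification, feature/target registry and the fitted state of each
#' output regressor (gradient-boosting models through their own raw
#' serialization so they survive across sessions). The round trip
#' reproduces predictions exactly.
#'
#' @param object A `growth_fit`.
#' @param path File path for the archive.
#' @return `save_growth_model()` returns `path` invisibly;
#'   `load_growth_model()` returns a `growth_fit`.
#' @export
save_growth_model <- function(object, path) {
  if (!inherits(object, "growth_fit")) abort("object must be a growth_fit")
  fits <- lapply(object$fits, function(fit) {
    if (fit$type == "xgb") {
      list(type = "xgb_raw", raw = xgboost::xgb.save.raw(fit$model))
    } else {
      fit
    }
  })
  archive <- list(
    format = "graftlight_growth_model", version = 1L,
    spec = object$spec, features = object$features,
    targets = object$targets, n_train = object$n_train,
    train_time_s = object$train_time_s, fits = fits
  )
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_growth_model
#' @export
load_growth_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format, "graftlight_growth_model")) {
    abort("file is not a graftlight growth-model archive")
  }
  fits <- lapply(archive$fits, function(fit) {
    if (identical(fit$type, "xgb_raw")) {
      list(type = "xgb", model = xgboost::xgb.load.raw(fit$raw))
    } else {
      fit
    }
  })
  structure(
    list(spec = archive$spec, fits = fits, features = archive$features,
         targets = archive$targets, n_train = archive$n_train,
         train_time_s = archive$train_time_s),
    class = "growth_fit"
  )
}
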