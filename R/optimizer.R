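#' Search bounds for inverse recipe design
#'
#' The box the designer searches: red and blue intensity 50--300 umol
#' m-2 s-1, photoperiod 10--18 h/d, cultivation length 3--40 days. An
#' optional red/blue ratio constraint can be added as a box on the ratio
#' (enforced by penalty); it is off by default.
#'
#' @param red,blue Intensity bounds (umol m-2 s-1).
#' @param photoperiod Photoperiod bounds (h/d).
#' @param days Cultivation-length bounds (days).
#' @param ratio Optional `c(lo, hi)` bounds on red/blue.
#' @return A list of class `"search_bounds"`.
#' @export
search_bounds <- function(red = c(50, 300), blue = c(50, 300),
                          photoperiod = c(10, 18), days = c(3, 40),
                          ratio = NULL) {
  for (b in list(red, blue, photoperiod, days)) {
    if (length(b) != 2 || b[1] >= b[2]) abort("each bound needs lo < hi")
  }
  if (!is.null(ratio) && (length(ratio) != 2 || ratio[1] >= ratio[2])) {
    abort("ratio bounds need lo < hi")
  }
  structure(list(red = red, blue = blue, photoperiod = photoperiod,
                 days = days, ratio = ratio),
            class = "search_bounds")
}

#' Prediction error of a candidate recipe
#'
#' Euclidean distance, in millimetres, between the forward model's
#' predicted (hypocotyl length, stem diameter) at a candidate
#' (recipe, days) and the target morphology.
#'
#' @param model A `growth_fit`.
#' @param candidates Tibble or matrix with columns/order `red_umol`,
#'   `blue_umol`, `photoperiod_h`, `day`.
#' @param target Numeric `c(hypocotyl_mm, stem_mm)` or a list/tibble with
#'   those names.
#' @return Numeric vector of Euclidean errors.
#' @export
prediction_error <- function(model, candidates, target) {
  target <- as_target(target)
  if (is.matrix(candidates)) {
    colnames(candidates) <- growth_features
  }
  pred <- predict(model, candidates)
  sqrt((pred$hypocotyl_mm - target[1])^2 + (pred$stem_mm - target[2])^2)
}

as_target <- function(target) {
  if (is.list(target) || is.data.frame(target)) {
    target <- c(target$hypocotyl_mm[1], target$stem_mm[1])
  }
  if (length(target) != 2 || any(!is.finite(target))) {
    abort("target must supply hypocotyl_mm and stem_mm")
  }
  if (target[1] < 0 || target[1] > 150 || target[2] < 0 || target[2] > 5) {
    abort("target morphology outside admissible ranges (0-150 mm, 0-5 mm)")
  }
  as.numeric(target)
}

#' Stage 1: find all candidate recipes within the error threshold
#'
#' Differential-evolution minimization of the prediction error over
#' (red, blue, photoperiod, days), archiving every evaluated candidate
#' whose error is below the threshold. An optional red/blue ratio box is
#' enforced by a smooth penalty. Finding no feasible candidate is an
#' explicit result (with the best error found), not an exception.
#'
#' @param model A `growth_fit`.
#' @param target Target morphology (see [prediction_error()]).
#' @param bounds A [search_bounds()].
#' @param config A [de_config()].
#' @param error_threshold Feasibility threshold on the Euclidean error
#'   (mm).
#' @param support Optional matrix/tibble of training feature rows
#'   (`red_umol`, `blue_umol`, `photoperiod_h`, `day`). When given, the
#'   search is confined to the surrogate's validity region: candidates
#'   are penalized by their scaled distance to the nearest training
#'   point beyond `support_threshold`, and feasible candidates must lie
#'   within the threshold. A tree-based surrogate is only trustworthy
#'   near its training support, so inverse designs meant to drive a real
#'   cultivation should use this.
#' @param support_threshold Normalized distance (fraction of each bound
#'   range) within which a candidate counts as supported.
#' @param support_weight Penalty (mm per unit excess distance) applied
#'   in the search objective.
#' @export
stage1_search <- function(model, target, bounds = search_bounds(),
                          config = de_config(), error_threshold = 0.3,
                          support = NULL, support_threshold = 0.05,
                          support_weight = 20) {
  target <- as_target(target)
  lower <- c(bounds$red[1], bounds$blue[1], bounds$photoperiod[1],
             bounds$days[1])
  upper <- c(bounds$red[2], bounds$blue[2], bounds$photoperiod[2],
             bounds$days[2])

  sup <- NULL
  if (!is.null(support)) {
    sup <- as.matrix(as_tibble(support)[, growth_features])
    sup <- sweep(sup, 2, upper - lower, "/")
  }
  support_dist <- function(X) {
    Xs <- sweep(X, 2, upper - lower, "/")
    apply(Xs, 1, function(x) {
      sqrt(min(colSums((t(sup) - x)^2)))
    })
  }

  fn <- function(X) {
    err <- prediction_error(model, X, target)
    if (!is.null(bounds$ratio)) {
      ratio <- X[, 1] / X[, 2]
      viol <- pmax(bounds$ratio[1] - ratio, 0) +
        pmax(ratio - bounds$ratio[2], 0)
      err <- err + 10 * viol
    }
    if (!is.null(sup)) {
      err <- err + support_weight * pmax(support_dist(X) - support_threshold, 0)
    }
    err
  }

  res <- differential_evolution(fn, lower, upper, config,
                                collect_below = error_threshold)
  feasible <- tibble()
  if (nrow(res$archive) > 0) {
    cand <- res$archive
    names(cand) <- c("red_umol", "blue_umol", "photoperiod_h", "days",
                     "error_continuous")
    # feasibility holds at the integer day actually cultivated
    cand$day_int <- round(cand$days)
    Xint <- as.matrix(tibble(
      red_umol = cand$red_umol, blue_umol = cand$blue_umol,
      photoperiod_h = cand$photoperiod_h, day = cand$day_int
    ))
    cand$error <- prediction_error(model, Xint, target)
    if (!is.null(sup)) {
      cand <- cand[support_dist(Xint) <= support_threshold, , drop = FALSE]
    }
    feasible <- cand %>%
      filter(.data$error < error_threshold) %>%
      distinct(.data$red_umol, .data$blue_umol, .data$photoperiod_h,
               .data$days, .keep_all = TRUE)
  }
  list(feasible = feasible, best = res$par, best_error = res$value,
       trace = res$trace, converged = res$converged)
}

#' Stage 2: shortest cultivation among feasible candidates
#'
#' Selects, among the stage-one feasible candidates, the one needing the
#' fewest days; ties are broken by smaller error, then by lower total
#' intensity (energy use).
#'
#' @param feasible Tibble from [stage1_search()]`$feasible`.
#' @return One-row tibble, or an empty tibble if no candidate is
#'   feasible.
#' @export
stage2_min_days <- function(feasible) {
  if (nrow(feasible) == 0) return(feasible)
  feasible %>%
    arrange(.data$day_int, .data$error,
            .data$red_umol + .data$blue_umol) %>%
    slice(1)
}

#' Two-stage inverse design of a light recipe
#'
#' Given a target morphology, finds the light recipe and the minimal
#' number of cultivation days such that the forward model's prediction
#' lies within the error threshold of the target: stage one collects
#' every candidate the evolutionary search visits whose Euclidean
#' prediction error is below the threshold, stage two filters that set
#' for the shortest cultivation.
#'
#' @param model A `growth_fit`.
#' @param target Target morphology, e.g. `c(hypocotyl_mm = 50, stem_mm = 3)`.
#' @param bounds A [search_bounds()].
#' @param config A [de_config()].
#' @param error_threshold Feasibility threshold (mm).
#' @param support,support_threshold,support_weight Optional trust-region
#'   restriction to the model's training support (see
#'   [stage1_search()]); off by default.
#' @return An object of class `"recipe_solution"`: list with `recipe`
#'   (one-row tibble), `days` (integer), `days_continuous`, `predicted`
#'   (tibble), `error`, `feasible` (logical), `ratio` (red/blue),
#'   `target`, `trace`, `n_feasible`, `best_error`.
#' @examples
#' \donttest{
#' d <- generate_design_dataset(n_per_treatment = 2, seed = 42)
#' m <- fit_growth_model(d, model_spec("gradient_boosting"))
#' design_recipe(m, c(hypocotyl_mm = 50, stem_mm = 3))
#' }
#' @export
design_recipe <- function(model, target, bounds = search_bounds(),
                          config = de_config(), error_threshold = 0.3,
                          support = NULL, support_threshold = 0.05,
                          support_weight = 20) {
  target <- as_target(target)
  s1 <- stage1_search(model, target, bounds, config, error_threshold,
                      support, support_threshold, support_weight)
  pick <- stage2_min_days(s1$feasible)

  if (nrow(pick) == 0) {
    return(structure(
      list(recipe = NULL, days = NA_integer_, days_continuous = NA_real_,
           predicted = NULL, error = s1$best_error, feasible = FALSE,
           ratio = NA_real_, target = target, trace = s1$trace,
           n_feasible = 0L, best_error = s1$best_error, best = s1$best),
      class = "recipe_solution"
    ))
  }

  recipe <- light_recipe(pick$red_umol, pick$blue_umol, pick$photoperiod_h)
  pred <- predict(model, tibble(
    red_umol = pick$red_umol, blue_umol = pick$blue_umol,
    photoperiod_h = pick$photoperiod_h, day = pick$day_int
  ))
  structure(
    list(recipe = recipe, days = as.integer(pick$day_int),
         days_continuous = pick$days, predicted = pred,
         error = pick$error, feasible = TRUE,
         ratio = recipe_ratio(recipe), target = target, trace = s1$trace,
         n_feasible = nrow(s1$feasible), best_error = s1$best_error,
         best = s1$best),
    class = "recipe_solution"
  )
}

#' Red/blue ratio of a recipe
#'
#' @param recipe A recipe tibble, or the red intensity when `blue` is
#'   given.
#' @param blue Optional blue intensity.
#' @param digits Rounding for the presentation value.
#' @return The ratio red/blue; `format_ratio()` gives the two-decimal
#'   presentation.
#' @examples
#' recipe_ratio(55.51, 151.42)          # 0.3666...
#' format_ratio(recipe_ratio(55.51, 151.42))  # "0.37"
#' @export
recipe_ratio <- function(recipe, blue = NULL) {
  if (is.null(blue)) {
    red <- recipe$red_umol
    blue <- recipe$blue_umol
  } else {
    red <- recipe
  }
  if (any(blue == 0)) abort("red/blue ratio undefined when blue = 0")
  red / blue
}

#' @rdname recipe_ratio
#' @export
format_ratio <- function(recipe, digits = 2) {
  format(round(recipe, digits), nsmall = digits)
}

#' @export
print.recipe_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("<recipe_solution> infeasible; best error ",
        format(round(x$best_error, 4)), " mm\n", sep = "")
    return(invisible(x))
  }
  cat("<recipe_solution> feasible (", x$n_feasible, " candidates)\n",
      "  red ", format(round(x$recipe$red_umol, 2)),
      " umol, blue ", format(round(x$recipe$blue_umol, 2)),
      " umol, photoperiod ", format(round(x$recipe$photoperiod_h, 2)),
      " h/d, ratio ", format_ratio(x$ratio), "\n",
      "  days ", x$days, ", error ", format(round(x$error, 4)), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy recipe_solution
tidy.recipe_solution <- function(x, ...) {
  if (!x$feasible) {
    return(tibble(feasible = FALSE, error = x$best_error))
  }
  bind_cols(
    x$recipe,
    tibble(days = x$days, days_continuous = x$days_continuous,
           ratio = x$ratio, error = x$error, feasible = TRUE,
           predicted_hypocotyl_mm = x$predicted$hypocotyl_mm,
           predicted_stem_mm = x$predicted$stem_mm,
           target_hypocotyl_mm = x$target[1],
           target_stem_mm = x$target[2])
  )
}
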