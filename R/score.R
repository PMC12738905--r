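#' Construct a weight vector over indicators
#'
#' A weight vector is a tibble with columns `indicator`, `weight` and
#' `method` ("ahp", "entropy", "combined", "uniform" or a user tag).
#' Weights must sum to 1 (tolerance 1e-9); AHP and entropy weights are in
#' addition required non-negative when produced by the package.
#'
#' @param indicator Character vector of indicator names.
#' @param weight Numeric weights summing to 1.
#' @param method Single tag recording how the weights were obtained.
#' @return A weight tibble.
#' @export
weight_vector <- function(indicator, weight, method = "user") {
  if (length(indicator) != length(weight)) {
    abort("indicator and weight must have the same length")
  }
  if (anyDuplicated(indicator)) abort("duplicated indicator names in weights")
  if (any(!is.finite(weight))) abort("weights must be finite")
  if (abs(sum(weight) - 1) > 1e-9) {
    abort(paste0("weights must sum to 1 (got ", format(sum(weight)), ")"))
  }
  tibble(indicator = as.character(indicator),
         weight = as.numeric(weight),
         method = method)
}

#' Uniform weights over a registry
#' @param registry An indicator registry.
#' @return A weight tibble with equal weights.
#' @export
uniform_weights <- function(registry = indicator_registry()) {
  m <- nrow(registry)
  weight_vector(registry$indicator, rep(1 / m, m), method = "uniform")
}

check_weights <- function(weights) {
  if (!all(c("indicator", "weight") %in% names(weights))) {
    abort("weights must have columns 'indicator' and 'weight'")
  }
  if (abs(sum(weights$weight) - 1) > 1e-9) {
    abort("weights must be normalized to sum 1")
  }
  invisible(weights)
}

#' Comprehensive grafting-suitability score
#'
#' The comprehensive score of a seedling is the weighted sum of its
#' standardized indicator values, `sum(T_j * w_j)`. With normalized
#' weights and standardized values in \[0, 1\] the maximum attainable
#' score is 1.
#'
#' @param standardized Named numeric vector (or single-row data frame) of
#'   standardized values in \[0, 1\], names matching the weight table.
#' @param weights A weight tibble (see [weight_vector()]).
#' @return A single score in \[0, 1\].
#' @examples
#' reg <- indicator_registry()
#' w <- uniform_weights(reg)
#' comprehensive_score(setNames(rep(1, 12), reg$indicator), w)
#' @export
comprehensive_score <- function(standardized, weights) {
  check_weights(weights)
  if (is.data.frame(standardized)) {
    standardized <- unlist(standardized[1, , drop = TRUE])
  }
  missing <- setdiff(weights$indicator, names(standardized))
  extra <- setdiff(names(standardized), weights$indicator)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "standardized values and weights disagree on indicators",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))
    ))
  }
  sum(standardized[weights$indicator] * weights$weight)
}

#' Score seedlings for grafting suitability
#'
#' Standardizes every indicator column of a measurement table and appends
#' the weighted comprehensive score as a `score` column. Columns not named
#' in the weight table pass through untouched (treatment ids etc.).
#'
#' @param data Wide measurement table, one row per seedling.
#' @param registry Indicator registry.
#' @param weights Weight tibble; defaults to uniform weights over the
#'   registry.
#' @return The input tibble with an added `score` column.
#' @export
score_seedlings <- function(data, registry = indicator_registry(),
                            weights = uniform_weights(registry)) {
  check_weights(weights)
  missing <- setdiff(weights$indicator, names(data))
  if (length(missing) > 0) {
    abort(paste0("measurement table lacks indicator column(s): ",
                 paste(missing, collapse = ", ")))
  }
  std <- standardize_measurements(data, registry)
  score <- as.matrix(std[, weights$indicator]) %*% weights$weight
  std$score <- as.numeric(score)
  std
}

#' Score a cohort of seedlings and summarize by group
#'
#' Scores each seedling with [score_seedlings()] and averages the
#' comprehensive scores, optionally per treatment group — the mechanism
#' used to rank light-recipe transition timings. Two aggregation routes
#' are available: score each seedling then average (`"per_seedling"`,
#' default) or average the raw indicators per group first and score the
#' group mean (`"cohort_mean"`).
#'
#' @param data Wide measurement table.
#' @param registry Indicator registry.
#' @param weights Weight tibble.
#' @param group Optional name of a grouping column (e.g. a treatment id).
#' @param method `"per_seedling"` or `"cohort_mean"`.
#' @return A tibble with one row per group (or one row overall) holding
#'   `n` and `mean_score`. The per-seedling scores are attached as the
#'   `"scores"` attribute when `method = "per_seedling"`.
#' @export
score_cohort <- function(data, registry = indicator_registry(),
                         weights = uniform_weights(registry),
                         group = NULL,
                         method = c("per_seedling", "cohort_mean")) {
  method <- match.arg(method)
  if (nrow(data) == 0) abort("empty cohort")
  if (method == "per_seedling") {
    scored <- score_seedlings(data, registry, weights)
    if (is.null(group)) {
      out <- tibble(n = nrow(scored), mean_score = mean(scored$score))
    } else {
      out <- scored %>%
        group_by(.data[[group]]) %>%
        summarise(n = n(), mean_score = mean(.data$score), .groups = "drop")
    }
    attr(out, "scores") <- scored
    out
  } else {
    grouped <- if (is.null(group)) {
      data %>%
        summarise(across(dplyr::all_of(weights$indicator), mean),
                  n = n())
    } else {
      data %>%
        group_by(.data[[group]]) %>%
        summarise(across(dplyr::all_of(weights$indicator), mean),
                  n = n(), .groups = "drop")
    }
    scored <- score_seedlings(grouped, registry, weights)
    scored %>%
      rename(mean_score = "score") %>%
      select(dplyr::any_of(c(group, "n", "mean_score")))
  }
}

#' Read / write weight tables
#'
#' Weights round-trip through a two-column CSV (`indicator`, `weight`)
#' with an optional `method` column.
#'
#' @param path Path to a CSV file.
#' @param weights A weight tibble.
#' @return `read_weights()` returns a weight tibble; `write_weights()`
#'   returns `path` invisibly.
#' @export
read_weights <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  weight_vector(w$indicator, w$weight,
                method = if ("method" %in% names(w)) w$method[1] else "user")
}

#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
  check_weights(weights)
  readr::write_csv(weights, path)
  invisible(path)
}
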