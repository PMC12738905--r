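#' Standardize indicator values to the unit interval
#'
#' Measured seedling indicators differ in unit and in direction (larger
#' better, smaller better, or best at a target). Before weighting, every
#' value is mapped to a dimensionless standardized value `T` in \[0, 1\]
#' with 1 always meaning "most favourable for grafting":
#'
#' * positive: `T = (v - L_min) / (L_max - L_min)`
#' * negative: `T = (L_max - v) / (L_max - L_min)`
#' * target value: `T = 1 - |v - a| / max(a - L_min, L_max - a)`
#' * target range: `T = 1` inside `[s_min, s_max]`, linear ramps down to 0
#'   at the admissible limits, and 0 outside them.
#'
#' Here `L_min`/`L_max` are the admissible range, `a` the target value and
#' `s_min`/`s_max` the target range. For the first three kinds the
#' admissible range is an admissibility contract: values outside it raise
#' an error naming the indicator. For the target-range kind, out-of-range
#' values score 0 (the ramp's outer branch), so no error is raised. When a
#' ramp end coincides with the admissible limit (as for moisture content,
#' whose target range fills its admissible range) that ramp branch is empty
#' and no division by zero occurs.
#'
#' @param v Numeric vector of measured values, in the indicator's unit.
#' @param spec A single-row registry tibble (or list with the same fields)
#'   describing one indicator.
#' @return Numeric vector of standardized values in \[0, 1\].
#' @seealso [indicator_registry()], [standardize_measurements()]
#' @examples
#' reg <- indicator_registry()
#' standardize_value(c(0, 50, 150), reg[reg$indicator == "hypocotyl_length", ])
#' @export
standardize_value <- function(v, spec) {
  spec <- as.list(spec)
  switch(spec$kind,
    positive = standardize_positive(v, spec),
    negative = standardize_negative(v, spec),
    interval_target_value = standardize_target_value(v, spec),
    interval_target_range = standardize_target_range(v, spec),
    abort(paste0("unknown indicator kind: ", spec$kind))
  )
}

check_admissible <- function(v, spec) {
  spec <- as.list(spec)
  if (any(!is.finite(v))) {
    abort(paste0("indicator '", spec$indicator,
                 "': non-finite or missing value"))
  }
  if (any(v < spec$range_min | v > spec$range_max)) {
    bad <- v[v < spec$range_min | v > spec$range_max][1]
    abort(paste0("indicator '", spec$indicator, "': value ", format(bad),
                 " outside admissible range [", spec$range_min, ", ",
                 spec$range_max, "] ", spec$unit))
  }
  invisible(v)
}

#' @rdname standardize_value
#' @export
standardize_positive <- function(v, spec) {
  spec <- as.list(spec)
  check_admissible(v, spec)
  (v - spec$range_min) / (spec$range_max - spec$range_min)
}

#' @rdname standardize_value
#' @export
standardize_negative <- function(v, spec) {
  spec <- as.list(spec)
  check_admissible(v, spec)
  (spec$range_max - v) / (spec$range_max - spec$range_min)
}

#' @rdname standardize_value
#' @export
standardize_target_value <- function(v, spec) {
  spec <- as.list(spec)
  check_admissible(v, spec)
  denom <- max(spec$target - spec$range_min, spec$range_max - spec$target)
  1 - abs(v - spec$target) / denom
}

#' @rdname standardize_value
#' @export
standardize_target_range <- function(v, spec) {
  spec <- as.list(spec)
  if (any(!is.finite(v))) {
    abort(paste0("indicator '", spec$indicator,
                 "': non-finite or missing value"))
  }
  out <- numeric(length(v))
  inside <- v >= spec$target_min & v <= spec$target_max
  out[inside] <- 1
  lo <- v >= spec$range_min & v < spec$target_min
  if (any(lo)) {
    # empty branch when target_min == range_min (lo is then all FALSE)
    out[lo] <- (v[lo] - spec$range_min) / (spec$target_min - spec$range_min)
  }
  hi <- v > spec$target_max & v <= spec$range_max
  if (any(hi)) {
    out[hi] <- (spec$range_max - v[hi]) / (spec$range_max - spec$target_max)
  }
  out
}

#' Standardize a table of seedling measurements
#'
#' Takes a wide table with one row per seedling and one column per
#' indicator (matching registry names; any other columns are treated as
#' identifiers and passed through) and replaces each indicator column with
#' its standardized value in \[0, 1\].
#'
#' @param data A data frame of measurements, one column per indicator.
#' @param registry An indicator registry; defaults to [indicator_registry()].
#' @return A tibble of the same shape with standardized indicator columns.
#' @export
standardize_measurements <- function(data, registry = indicator_registry()) {
  data <- as_tibble(data)
  validate_registry(registry)
  present <- intersect(registry$indicator, names(data))
  if (length(present) == 0) {
    abort("no measurement column matches a registry indicator")
  }
  for (name in present) {
    spec <- registry[registry$indicator == name, ]
    data[[name]] <- standardize_value(data[[name]], spec)
  }
  data
}
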