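#' Indicator registry for grafting-suitability scoring
#'
#' The registry describes every indicator entering the comprehensive
#' grafting-suitability score: its directionality kind, its admissible range
#' (values outside it are either rejected or scored 0, depending on kind),
#' and, for interval-type indicators, the target value or target range the
#' grafting machine requires.
#'
#' Four kinds are supported:
#' \describe{
#'   \item{`positive`}{larger is better (e.g. fresh weight).}
#'   \item{`negative`}{smaller is better (e.g. shear strength).}
#'   \item{`interval_target_value`}{best at a single target value `target`
#'     (e.g. hypocotyl length at the machine's clamping height).}
#'   \item{`interval_target_range`}{best anywhere inside
#'     `[target_min, target_max]` (e.g. stem diameter inside the grafting
#'     clip's tolerance).}
#' }
#'
#' `indicator_registry()` returns the default 12-indicator registry for a
#' clamp-and-cut tomato grafting machine: hypocotyl length targets 50 mm
#' within an admissible 0--150 mm, stem diameter targets 2.7--3.3 mm within
#' 0--5 mm, and moisture content's target range coincides with its
#' admissible 85--95 % range. Different machines can redefine targets by
#' editing the registry (see [read_indicator_registry()]).
#'
#' @return A tibble with columns `indicator`, `kind`, `range_min`,
#'   `range_max`, `target`, `target_min`, `target_max`, `unit`.
#' @examples
#' indicator_registry()
#' @export
indicator_registry <- function() {
  reg <- tibble::tribble(
    ~indicator,                 ~kind,                    ~range_min, ~range_max, ~target, ~target_min, ~target_max, ~unit,
    "hypocotyl_length",         "interval_target_value",  0,          150,        50,      NA,          NA,          "mm",
    "stem_diameter",            "interval_target_range",  0,          5,          NA,      2.7,         3.3,         "mm",
    "moisture_content",         "interval_target_range",  85,         95,         NA,      85,          95,          "%",
    "fresh_weight",             "positive",               0,          5,          NA,      NA,          NA,          "g",
    "shoot_dry_weight",         "positive",               0,          0.5,        NA,      NA,          NA,          "g",
    "root_dry_weight",          "positive",               0,          0.5,        NA,      NA,          NA,          "g",
    "plant_height",             "negative",               0,          250,        NA,      NA,          NA,          "mm",
    "seedling_strength_index",  "positive",               0,          1,          NA,      NA,          NA,          "-",
    "radial_compression_force", "positive",               0,          50,         NA,      NA,          NA,          "N",
    "axial_compression_force",  "positive",               0,          15,         NA,      NA,          NA,          "N",
    "bending_strength",         "positive",               0,          5,          NA,      NA,          NA,          "MPa",
    "shear_strength",           "negative",               0,          5,          NA,      NA,          NA,          "MPa"
  )
  validate_registry(reg)
}

indicator_kinds <- c(
  "positive", "negative", "interval_target_value", "interval_target_range"
)

#' Validate an indicator registry
#'
#' Checks the structural invariants of a registry tibble: known kinds,
#' `range_min < range_max`, a target value inside the admissible range for
#' `interval_target_value` indicators, and an ordered target range inside
#' the admissible range for `interval_target_range` indicators.
#'
#' @param registry A registry tibble (see [indicator_registry()]).
#' @return The registry, invisibly unchanged, for piping.
#' @export
validate_registry <- function(registry) {
  required <- c("indicator", "kind", "range_min", "range_max",
                "target", "target_min", "target_max", "unit")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(registry$indicator)) {
    abort("registry has duplicated indicator names")
  }
  bad_kind <- setdiff(unique(registry$kind), indicator_kinds)
  if (length(bad_kind) > 0) {
    abort(paste0("unknown indicator kind(s): ",
                 paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    if (!is.finite(row$range_min) || !is.finite(row$range_max) ||
        row$range_min >= row$range_max) {
      abort(paste0("indicator '", row$indicator,
                   "': range_min must be < range_max"))
    }
    if (row$kind == "interval_target_value") {
      if (!is.finite(row$target) ||
          row$target < row$range_min || row$target > row$range_max) {
        abort(paste0("indicator '", row$indicator,
                     "': target must lie inside [range_min, range_max]"))
      }
    }
    if (row$kind == "interval_target_range") {
      if (!is.finite(row$target_min) || !is.finite(row$target_max) ||
          row$target_min > row$target_max ||
          row$target_min < row$range_min || row$target_max > row$range_max) {
        abort(paste0("indicator '", row$indicator,
                     "': need range_min <= target_min <= target_max <= range_max"))
      }
    }
  }
  registry
}

#' Read / write an indicator registry
#'
#' The registry round-trips through a plain CSV file with one row per
#' indicator and the same columns as [indicator_registry()], so alternative
#' grafting machines can ship their own target configuration.
#'
#' @param path Path to a CSV file.
#' @param registry A registry tibble.
#' @return `read_indicator_registry()` returns a validated registry tibble;
#'   `write_indicator_registry()` returns `path` invisibly.
#' @export
read_indicator_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           indicator = "c", kind = "c", unit = "c",
                           .default = "d"
                         ))
  validate_registry(as_tibble(reg))
}

#' @rdname read_indicator_registry
#' @export
write_indicator_registry <- function(registry, path) {
  validate_registry(registry)
  readr::write_csv(registry, path)
  invisible(path)
}
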