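#' Single-factor and LRTT design treatments
#'
#' The treatment structure of the light-element experiment the twin
#' emulates: 5 light-quality levels (R:B = 100:0, 25:75, 50:50, 75:25,
#' 0:100 at 50 umol, 12 h/d), 5 intensity levels (50--250 umol at
#' R:B = 50:50, 12 h/d), 5 photoperiods (10--18 h/d at 200 umol,
#' R:B = 50:50), and 5 light-recipe transition timings (switch on days
#' 5--9 from the elongation recipe R:B = 3:1 at 150 umol, 18 h/d to the
#' thickening recipe R:B = 1:3 at 200 umol, 18 h/d).
#'
#' @return A tibble with one row per schedule segment, columns
#'   `treatment_id`, `factor` and the schedule columns.
#' @export
design_treatments <- function() {
  quality <- purrr::map_dfr(
    list(c(100, 0), c(25, 75), c(50, 50), c(75, 25), c(0, 100)),
    function(rb) {
      tibble(
        treatment_id = paste0("Q_", rb[1], ":", rb[2]), factor = "quality",
        start_day = 0, red_umol = 50 * rb[1] / 100,
        blue_umol = 50 * rb[2] / 100, photoperiod_h = 12
      )
    }
  )
  intensity <- purrr::map_dfr(c(50, 100, 150, 200, 250), function(i) {
    tibble(
      treatment_id = paste0("I_", i), factor = "intensity",
      start_day = 0, red_umol = i / 2, blue_umol = i / 2, photoperiod_h = 12
    )
  })
  photoperiod <- purrr::map_dfr(c(10, 12, 14, 16, 18), function(p) {
    tibble(
      treatment_id = paste0("P_", p), factor = "photoperiod",
      start_day = 0, red_umol = 100, blue_umol = 100, photoperiod_h = p
    )
  })
  lrtt <- purrr::map_dfr(5:9, function(d) {
    tibble(
      treatment_id = paste0("LRTT_", d), factor = "lrtt",
      start_day = c(0, d),
      red_umol = c(112.5, 50), blue_umol = c(37.5, 150),
      photoperiod_h = c(18, 18)
    )
  })
  bind_rows(quality, intensity, photoperiod, lrtt)
}

#' Generate the twin design dataset
#'
#' Simulates every design treatment (see [design_treatments()]) with
#' `n_per_treatment` independent seedlings each, sampled on days 5, 10,
#' 15, 20, 25 and 30 after emergence — the sampling plan of the emulated
#' experiment. The record count is
#' `20 treatments x 6 days x n_per_treatment` (15 single-factor arms
#' plus 5 transition timings), so `n_per_treatment = 6` gives 720
#' records per organ role, the order of magnitude of a real
#' single-season campaign.
#'
#' @param params Twin parameters.
#' @param n_per_treatment Seedlings measured per treatment and day.
#' @param seed Integer seed controlling replicate rate factors and
#'   measurement noise.
#' @param role `"rootstock"` or `"scion"`.
#' @param sample_days Days after emergence on which seedlings are
#'   measured.
#' @param noise Apply measurement noise?
#' @return A growth dataset tibble with columns `treatment_id`, `role`,
#'   `replicate`, `day`, `red_umol`, `blue_umol`, `photoperiod_h`,
#'   `hypocotyl_mm`, `stem_mm`, and `constant_recipe` (FALSE for
#'   recipe-transition treatments, whose light history a (recipe, day)
#'   record cannot fully express).
#' @examples
#' d <- generate_design_dataset(n_per_treatment = 1, seed = 1)
#' nrow(d)  # 120
#' @export
generate_design_dataset <- function(params = twin_params(),
                                    n_per_treatment = 6, seed = 42,
                                    role = c("rootstock", "scion"),
                                    sample_days = c(5, 10, 15, 20, 25, 30),
                                    noise = TRUE) {
  role <- match.arg(role)
  if (n_per_treatment < 1) abort("n_per_treatment must be >= 1")
  set.seed(seed)
  treatments <- design_treatments()
  ids <- unique(treatments$treatment_id)
  max_day <- max(sample_days)

  purrr::map_dfr(ids, function(id) {
    sched <- treatments %>%
      filter(.data$treatment_id == id) %>%
      select("start_day", "red_umol", "blue_umol", "photoperiod_h")
    purrr::map_dfr(seq_len(n_per_treatment), function(rep_i) {
      rf <- max(rnorm(1, 1, params$rate_cv), 0.5)
      traj <- simulate_trajectory(sched, days = max_day, params = params,
                                  noise = noise, role = role,
                                  rate_factor = rf)
      traj %>%
        filter(.data$day %in% sample_days) %>%
        mutate(treatment_id = id, replicate = rep_i,
               constant_recipe = nrow(sched) == 1) %>%
        select("treatment_id", "role", "replicate", "day",
               "red_umol", "blue_umol", "photoperiod_h",
               "hypocotyl_mm", "stem_mm", "constant_recipe")
    })
  })
}

#' Read / write a growth dataset
#'
#' Growth datasets round-trip through CSV with the column layout of
#' [generate_design_dataset()].
#'
#' @param path Path to a CSV file.
#' @param data A growth dataset tibble.
#' @return `read_growth_dataset()` returns a tibble; `write_growth_dataset()`
#'   returns `path` invisibly.
#' @export
read_growth_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("day", "red_umol", "blue_umol", "photoperiod_h",
            "hypocotyl_mm", "stem_mm")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    abort(paste0("growth dataset lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(d)
}

#' @rdname read_growth_dataset
#' @export
write_growth_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read / write twin parameters
#'
#' Twin parameters round-trip through a plain YAML file so alternative
#' fixture configurations can be shared.
#'
#' @param path Path to a YAML file.
#' @param params A `twin_params` object.
#' @return `read_twin_params()` returns a `twin_params` object;
#'   `write_twin_params()` returns `path` invisibly.
#' @export
read_twin_params <- function(path) {
  do.call(twin_params, yaml::read_yaml(path))
}

#' @rdname read_twin_params
#' @export
write_twin_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
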