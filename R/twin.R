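#' Light recipes and recipe schedules
#'
#' A light recipe is the triple (red intensity, blue intensity,
#' photoperiod) delivered by the LED array, in umol m-2 s-1 and hours per
#' day. A recipe schedule is an ordered set of recipes with start days,
#' the first starting at day 0 — the structure used for light-recipe
#' transition timing (LRTT) treatments, where an elongation-promoting
#' recipe is switched to a thickening-promoting one on a chosen day.
#'
#' @param red,blue Non-negative irradiances (umol m-2 s-1); not both zero.
#' @param photoperiod Hours of light per day, in (0, 24].
#' @return `light_recipe()`: a one-row tibble with columns `red_umol`,
#'   `blue_umol`, `photoperiod_h`.
#' @examples
#' light_recipe(150, 50, 18)  # R:B = 3:1 at 200 umol, long day
#' @export
light_recipe <- function(red, blue, photoperiod) {
  if (!is.finite(red) || !is.finite(blue) || red < 0 || blue < 0) {
    abort("red and blue intensities must be finite and non-negative")
  }
  if (red == 0 && blue == 0) abort("red and blue cannot both be zero")
  if (!is.finite(photoperiod) || photoperiod <= 0 || photoperiod > 24) {
    abort("photoperiod must lie in (0, 24] h/d")
  }
  tibble(red_umol = red, blue_umol = blue, photoperiod_h = photoperiod)
}

#' @param segments A list of `list(start_day = , recipe = )` pairs, or a
#'   data frame with columns `start_day`, `red_umol`, `blue_umol`,
#'   `photoperiod_h`. Start days must be strictly increasing and begin
#'   at 0.
#' @rdname light_recipe
#' @return `recipe_schedule()`: a tibble with columns `start_day`,
#'   `red_umol`, `blue_umol`, `photoperiod_h`.
#' @export
recipe_schedule <- function(segments) {
  if (is.data.frame(segments)) {
    sched <- as_tibble(segments)
  } else {
    sched <- purrr::map_dfr(segments, function(s) {
      bind_cols(tibble(start_day = s$start_day), s$recipe)
    })
  }
  need <- c("start_day", "red_umol", "blue_umol", "photoperiod_h")
  if (!all(need %in% names(sched))) {
    abort(paste0("schedule needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(sched) == 0) abort("schedule must contain at least one segment")
  if (sched$start_day[1] != 0) abort("first schedule segment must start at day 0")
  if (any(diff(sched$start_day) <= 0)) {
    abort("schedule start days must be strictly increasing")
  }
  for (i in seq_len(nrow(sched))) {
    light_recipe(sched$red_umol[i], sched$blue_umol[i], sched$photoperiod_h[i])
  }
  sched
}

#' Recipe active on a given day
#' @param schedule A recipe schedule.
#' @param day Day after emergence.
#' @return One-row recipe tibble.
#' @export
active_recipe <- function(schedule, day) {
  i <- max(which(schedule$start_day <= day))
  schedule[i, c("red_umol", "blue_umol", "photoperiod_h")]
}

#' Parameters of the synthetic plant twin
#'
#' The plant twin is a synthetic tomato-seedling growth simulator used as
#' a test fixture: it generates hypocotyl-length and stem-diameter
#' trajectories with the qualitative light responses reported for tomato
#' seedlings, so that scoring, forward modelling, inverse design and
#' closed-loop control can be exercised end to end without glasshouse
#' data. It is explicitly not a mechanistic biological model.
#'
#' Both traits follow daily-step logistic growth that has essentially
#' saturated by the fourth week, as real seedlings have. Hypocotyl
#' elongation is rate-driven and path-dependent — it is fastest in the
#' elongation window (days 5--9 after emergence) and decays after a
#' maturation day, so a recipe transition leaves its history in the
#' final length. Stem thickening relaxes towards a light-determined
#' plateau. The environmental modifiers implement:
#'
#' * hypocotyl elongation increases with the red fraction, decreases
#'   with total intensity (Hill-type), and increases with photoperiod up
#'   to `photoperiod_saturation` then declines;
#' * the stem plateau increases with the blue fraction, increases with
#'   total intensity up to the photoinhibition threshold then declines,
#'   and increases mildly with photoperiod;
#' * monochromatic blue light adds a small hypocotyl elongation boost
#'   (a documented second-order effect, toggleable).
#'
#' Noise enters only at measurement: recorded values are the underlying
#' trait plus zero-truncated Gaussian error, and each simulated seedling
#' carries a small lognormal-like growth-rate factor so replicates differ
#' smoothly. Defaults are calibrated so that a fixed recipe near
#' (55 red, 151 blue, 14.4 h/d) reaches about 50 mm hypocotyl and 3 mm
#' stem diameter around day 25, and all design-point trajectories stay
#' inside the admissible 0--150 mm / 0--5 mm scoring ranges.
#'
#' @param ... Named overrides of the default parameters.
#' @return A named list of class `"twin_params"`.
#' @export
twin_params <- function(...) {
  p <- list(
    # initial sizes at emergence (mm) and admissible plateau caps (mm)
    hyp_init = 4, hyp_asym = 140,
    stem_init = 0.25, stem_asym = 4.6,
    # stem plateau scale and intrinsic rates (calibrated, see vignette)
    stem_asym_base = 2.60, hyp_rate = 0.37, stem_rate = 0.42,
    # hypocotyl elongation phase: maturation decay after maturation_day
    maturation_day = 13, maturation_tau = 5,
    # hypocotyl modifiers
    hyp_red_base = 0.55, hyp_red_gain = 0.9,       # in red fraction
    hyp_int_half = 180,                            # umol, Hill decline
    photoperiod_saturation = 16,                   # h/d
    hyp_photo_slope = 0.04, hyp_photo_decline = 0.06,
    elongation_window = c(5, 9), window_boost = 1.8,
    mono_blue_boost = 0.35, mono_blue = TRUE,
    # stem modifiers
    stem_blue_base = 1.2, stem_blue_gain = 0.1,    # in blue fraction
    stem_blue_excess = 0.65, stem_blue_decline = 0.8,  # monochromatic penalty
    photoinhibition_threshold = 260,               # umol, hump peak
    stem_photo_base = 0.7, stem_photo_slope = 0.0245,
    # plant-to-plant growth-vigour spread (plant-factory plug trays are
    # highly uniform; ~1 % on the daily rate gives a few % on final
    # hypocotyl length) and measurement noise
    rate_cv = 0.01,
    noise_hyp_mm = 0.5, noise_stem_mm = 0.03,
    # role differences: scions germinate later and grow slightly slower
    scion_rate_factor = 0.92
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown twin parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  if (p$hyp_asym > 150 || p$stem_asym > 5) {
    abort("asymptotes must stay inside the admissible scoring ranges")
  }
  if (p$noise_hyp_mm < 0 || p$noise_stem_mm < 0 || p$rate_cv < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(p, class = "twin_params")
}

# environmental rate multipliers ------------------------------------------

twin_hyp_multiplier <- function(params, red, blue, photoperiod) {
  f <- red / (red + blue)
  m_red <- params$hyp_red_base + params$hyp_red_gain * f
  if (params$mono_blue && red == 0 && blue > 0) {
    m_red <- m_red + params$mono_blue_boost
  }
  total <- red + blue
  m_int <- params$hyp_int_half / (params$hyp_int_half + total)
  ps <- params$photoperiod_saturation
  m_photo <- if (photoperiod <= ps) {
    1 + params$hyp_photo_slope * (photoperiod - 12)
  } else {
    1 + params$hyp_photo_slope * (ps - 12) -
      params$hyp_photo_decline * (photoperiod - ps)
  }
  m_red * m_int * max(m_photo, 0.05)
}

twin_stem_multiplier <- function(params, red, blue, photoperiod) {
  fb <- blue / (red + blue)
  # rises with blue fraction, but combined light beats near-monochromatic
  # blue: a linear decline sets in beyond stem_blue_excess
  m_blue <- params$stem_blue_base + params$stem_blue_gain * fb -
    params$stem_blue_decline * max(fb - params$stem_blue_excess, 0)
  total <- red + blue
  ith <- params$photoinhibition_threshold
  m_int <- (total / ith) * exp(1 - total / ith)  # hump, peak 1 at threshold
  m_photo <- params$stem_photo_base + params$stem_photo_slope * photoperiod
  m_blue * m_int * m_photo
}

# developmental phase factor for hypocotyl elongation: boosted in the
# elongation window (days 5-9), unity before/between, decaying after the
# maturation day — elongation is an early, largely irreversible process
twin_hyp_phase <- function(params, day) {
  if (day >= params$elongation_window[1] &&
      day <= params$elongation_window[2]) {
    return(params$window_boost)
  }
  if (day > params$maturation_day) {
    return(max(exp(-(day - params$maturation_day) / params$maturation_tau),
               0.02))
  }
  1
}

# one Euler day-step of the twin state under a recipe; `day` is the day
# being grown into. Hypocotyl growth is rate-driven (path-dependent, so
# recipe transitions leave their history in the final length); stem
# growth relaxes towards its light-determined plateau.
twin_step <- function(params, H, S, red, blue, photoperiod, day,
                      rate_scale = 1) {
  H <- unname(H); S <- unname(S)
  red <- unname(red); blue <- unname(blue); photoperiod <- unname(photoperiod)
  mH <- twin_hyp_multiplier(params, red, blue, photoperiod)
  phase <- twin_hyp_phase(params, day)
  H <- H + params$hyp_rate * mH * phase * rate_scale *
    H * max(1 - H / params$hyp_asym, 0)

  asym_S <- min(max(params$stem_asym_base *
                      twin_stem_multiplier(params, red, blue, photoperiod),
                    params$stem_init), params$stem_asym)
  S <- S + params$stem_rate * rate_scale * S * max(1 - S / asym_S, 0)
  c(H = H, S = S)
}

#' Simulate a seedling growth trajectory
#'
#' Runs the plant twin under a recipe schedule for a number of days and
#' returns the daily trajectory. With `noise = FALSE` and
#' `rate_factor = 1` the trajectory is deterministic, non-decreasing in
#' both traits and bounded by the asymptotes; with noise on, recorded
#' values are zero-truncated noisy measurements of the underlying state.
#'
#' @param schedule A recipe schedule (see [recipe_schedule()]); a single
#'   recipe tibble is promoted to a one-segment schedule.
#' @param days Number of days after emergence to simulate (>= 1).
#' @param params Twin parameters from [twin_params()].
#' @param seed Optional integer seed for reproducible noise.
#' @param noise Apply measurement noise to the recorded values?
#' @param role `"rootstock"` or `"scion"` (scions grow slightly slower).
#' @param rate_factor Per-plant growth-rate multiplier (replicate
#'   variation; 1 = nominal).
#' @return Tibble with one row per day 0..`days`: `day`, `red_umol`,
#'   `blue_umol`, `photoperiod_h` (recipe active that day),
#'   `hypocotyl_mm`, `stem_mm`, `role`, plus the noise-free
#'   `true_hypocotyl_mm`, `true_stem_mm`.
#' @examples
#' traj <- simulate_trajectory(light_recipe(100, 100, 12), days = 30,
#'                             noise = FALSE)
#' tail(traj, 3)
#' @export
simulate_trajectory <- function(schedule, days, params = twin_params(),
                                seed = NULL, noise = TRUE,
                                role = c("rootstock", "scion"),
                                rate_factor = 1) {
  role <- match.arg(role)
  if (!inherits(params, "twin_params")) abort("params must come from twin_params()")
  if (days < 1) abort("days must be >= 1")
  if (!"start_day" %in% names(schedule)) {
    schedule <- recipe_schedule(list(list(start_day = 0, recipe = schedule)))
  } else {
    schedule <- recipe_schedule(schedule)
  }
  if (!is.null(seed)) set.seed(seed)

  role_factor <- if (role == "scion") params$scion_rate_factor else 1
  H <- params$hyp_init
  S <- params$stem_init
  n <- days + 1
  out_H <- numeric(n); out_S <- numeric(n)
  out_H[1] <- H; out_S[1] <- S
  rec <- as.matrix(schedule[, c("red_umol", "blue_umol", "photoperiod_h")])
  starts <- schedule$start_day

  for (t in seq_len(days)) {
    seg <- max(which(starts <= t - 1))
    state <- twin_step(params, H, S, rec[seg, 1], rec[seg, 2], rec[seg, 3],
                       day = t, rate_scale = role_factor * rate_factor)
    H <- state[["H"]]
    S <- state[["S"]]
    out_H[t + 1] <- H
    out_S[t + 1] <- S
  }

  day <- 0:days
  seg_idx <- vapply(day, function(d) max(which(starts <= d)), integer(1))
  traj <- tibble(
    day = day,
    red_umol = rec[seg_idx, 1],
    blue_umol = rec[seg_idx, 2],
    photoperiod_h = rec[seg_idx, 3],
    true_hypocotyl_mm = out_H,
    true_stem_mm = out_S,
    role = role
  )
  if (noise) {
    traj$hypocotyl_mm <- measure_with_noise(traj$true_hypocotyl_mm,
                                            params$noise_hyp_mm)
    traj$stem_mm <- measure_with_noise(traj$true_stem_mm,
                                       params$noise_stem_mm)
  } else {
    traj$hypocotyl_mm <- traj$true_hypocotyl_mm
    traj$stem_mm <- traj$true_stem_mm
  }
  select(traj, "day", "red_umol", "blue_umol", "photoperiod_h",
         "hypocotyl_mm", "stem_mm", "true_hypocotyl_mm", "true_stem_mm",
         "role")
}

#' Noisy measurement of a trait
#'
#' Adds zero-truncated Gaussian measurement error, emulating the spread
#' of replicate caliper readings; `sd = 0` returns the value unchanged.
#'
#' @param true_value Numeric vector of true trait values (mm).
#' @param sd Measurement standard deviation (mm, >= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector, never negative.
#' @export
measure_with_noise <- function(true_value, sd, seed = NULL) {
  if (sd < 0) abort("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(true_value)
  pmax(true_value + rnorm(length(true_value), 0, sd), 0)
}
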