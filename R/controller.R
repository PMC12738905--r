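#' Relative deviation of a measurement from its prediction
#'
#' @param measured,predicted Positive trait values (mm).
#' @return `|measured - predicted| / predicted`.
#' @examples
#' relative_deviation(45, 50)  # 0.10
#' @export
relative_deviation <- function(measured, predicted) {
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    abort("predicted value must be positive")
  }
  abs(measured - predicted) / predicted
}

#' Closed-loop controller configuration
#'
#' The controller compares each day's measured morphology with the
#' forward model's prediction at the current recipe and day; when a
#' trait deviates by more than `deviation_threshold` (relative), the
#' recipe is moved one step in the corrective direction. Step sizes are
#' engineering choices (the directional rules themselves are fixed):
#' the ratio step reallocates a fraction of the total flux between red
#' and blue at constant intensity, the intensity step rescales the total
#' flux, and the photoperiod step lengthens or shortens the light cycle.
#' Recipes are always clipped to `bounds`.
#'
#' Relative deviations are ill-defined while the seedling is tiny: a
#' tenth of a millimetre on a day-2 stem is a 30 % "deviation" that no
#' camera can resolve and no grafting tolerance cares about. Control
#' therefore starts on `start_day` (the first sampling occasion of the
#' emulated protocol), and a violation must additionally exceed an
#' absolute floor on the trait (of the order of the imaging resolution
#' and the robot's absolute clamping tolerance).
#'
#' @param deviation_threshold Relative deviation (0--1) that triggers an
#'   adjustment; 10 % reflects a grafting robot's operational tolerance.
#' @param ratio_step Fraction of total flux reallocated per adjustment.
#' @param intensity_step Total-intensity step (umol m-2 s-1).
#' @param photoperiod_step Photoperiod step (h/d).
#' @param bounds A [search_bounds()] keeping recipes realizable.
#' @param start_day First day on which adjustments may be issued.
#' @param min_abs_hypocotyl_mm,min_abs_stem_mm Absolute deviation floors
#'   (mm) below which no action is taken.
#' @return A list of class `"controller_config"`.
#' @export
controller_config <- function(deviation_threshold = 0.10, ratio_step = 0.1,
                              intensity_step = 10, photoperiod_step = 0.5,
                              bounds = search_bounds(), start_day = 5,
                              min_abs_hypocotyl_mm = 2,
                              min_abs_stem_mm = 0.2) {
  if (deviation_threshold <= 0 || deviation_threshold >= 1) {
    abort("deviation_threshold must lie in (0, 1)")
  }
  if (ratio_step <= 0 || intensity_step <= 0 || photoperiod_step <= 0) {
    abort("step sizes must be positive")
  }
  structure(
    list(deviation_threshold = deviation_threshold, ratio_step = ratio_step,
         intensity_step = intensity_step, photoperiod_step = photoperiod_step,
         bounds = bounds, start_day = start_day,
         min_abs_hypocotyl_mm = min_abs_hypocotyl_mm,
         min_abs_stem_mm = min_abs_stem_mm),
    class = "controller_config"
  )
}

#' Decide the daily light-recipe adjustment
#'
#' Encodes the directional adjustment rules: when the hypocotyl is more
#' than the threshold *shorter* than predicted, increase the red ratio,
#' reduce intensity and shorten the photoperiod (and the opposite when
#' too long); when the stem is too *thin*, increase the blue ratio
#' (i.e. decrease the red ratio), increase intensity and extend the
#' photoperiod (opposite when too thick). Within the threshold on both
#' traits, hold everything. When both traits violate the threshold the
#' hypocotyl rule sets ratio and photoperiod and the stem rule sets
#' intensity — a hypocotyl outside the machine's tolerance fails the
#' graft outright, so it gets the spectral levers, while intensity is
#' the stronger stem lever.
#'
#' @param measurement List/tibble with `hypocotyl_mm`, `stem_mm`
#'   (measured).
#' @param predicted Same shape, the model's prediction for today.
#' @param config A [controller_config()].
#' @return One-row tibble: `red_ratio`, `intensity`, `photoperiod` (each
#'   `"increase"`, `"decrease"` or `"hold"`), `triggered_by` (`"none"`,
#'   `"hypocotyl"`, `"stem"`, `"both"`), `deviation_hypocotyl`,
#'   `deviation_stem`.
#' @export
decide_action <- function(measurement, predicted,
                          config = controller_config()) {
  m_h <- measurement$hypocotyl_mm[1]; m_s <- measurement$stem_mm[1]
  p_h <- predicted$hypocotyl_mm[1]; p_s <- predicted$stem_mm[1]
  dev_h <- relative_deviation(m_h, p_h)
  dev_s <- relative_deviation(m_s, p_s)
  thr <- config$deviation_threshold
  viol_h <- dev_h > thr && abs(m_h - p_h) > config$min_abs_hypocotyl_mm
  viol_s <- dev_s > thr && abs(m_s - p_s) > config$min_abs_stem_mm

  hold <- c(red_ratio = "hold", intensity = "hold", photoperiod = "hold")
  hyp_rule <- if (m_h < p_h) {
    c(red_ratio = "increase", intensity = "decrease", photoperiod = "decrease")
  } else {
    c(red_ratio = "decrease", intensity = "increase", photoperiod = "increase")
  }
  stem_rule <- if (m_s < p_s) {
    c(red_ratio = "decrease", intensity = "increase", photoperiod = "increase")
  } else {
    c(red_ratio = "increase", intensity = "decrease", photoperiod = "decrease")
  }

  act <- if (!viol_h && !viol_s) {
    hold
  } else if (viol_h && !viol_s) {
    hyp_rule
  } else if (!viol_h && viol_s) {
    stem_rule
  } else {
    c(red_ratio = hyp_rule[["red_ratio"]],
      intensity = stem_rule[["intensity"]],
      photoperiod = hyp_rule[["photoperiod"]])
  }
  triggered <- if (viol_h && viol_s) "both" else if (viol_h) "hypocotyl" else if (viol_s) "stem" else "none"

  tibble(red_ratio = act[["red_ratio"]], intensity = act[["intensity"]],
         photoperiod = act[["photoperiod"]], triggered_by = triggered,
         deviation_hypocotyl = dev_h, deviation_stem = dev_s)
}

#' Apply an adjustment action to a recipe
#'
#' Ratio moves reallocate `ratio_step` of the total flux from blue to
#' red (or back) at constant total intensity; the intensity move then
#' rescales the total by `intensity_step`; the photoperiod moves by
#' `photoperiod_step`. Every component is clipped to the configured
#' bounds (a step at a bound leaves the component unchanged).
#'
#' @param recipe One-row recipe tibble.
#' @param action Action tibble from [decide_action()].
#' @param config A [controller_config()].
#' @return Adjusted one-row recipe tibble.
#' @export
apply_action <- function(recipe, action, config = controller_config()) {
  b <- config$bounds
  total <- recipe$red_umol + recipe$blue_umol
  frac <- recipe$red_umol / total

  frac <- switch(action$red_ratio,
    increase = frac + config$ratio_step,
    decrease = frac - config$ratio_step,
    hold = frac
  )
  total <- switch(action$intensity,
    increase = total + config$intensity_step,
    decrease = total - config$intensity_step,
    hold = total
  )
  total <- min(max(total, b$red[1] + b$blue[1]), b$red[2] + b$blue[2])
  # keep both channels inside their bounds at this total
  frac_lo <- max(b$red[1] / total, 1 - b$blue[2] / total)
  frac_hi <- min(b$red[2] / total, 1 - b$blue[1] / total)
  frac <- min(max(frac, frac_lo), frac_hi)

  photo <- switch(action$photoperiod,
    increase = recipe$photoperiod_h + config$photoperiod_step,
    decrease = recipe$photoperiod_h - config$photoperiod_step,
    hold = recipe$photoperiod_h
  )
  photo <- min(max(photo, b$photoperiod[1]), b$photoperiod[2])

  light_recipe(frac * total, (1 - frac) * total, photo)
}

#' Run the daily closed-loop regulation against the plant twin
#'
#' Simulates the full control loop for one cultivation tray: a cohort of
#' `n_plants` twin seedlings (each with its own growth-vigour factor)
#' grows one day under the current recipe; the tray is imaged and the
#' cohort-mean morphology measured (per-plant measurement noise averages
#' accordingly); the forward model predicts today's morphology at the
#' current recipe; deviations are compared with the threshold, and the
#' recipe is adjusted by the directional rules when needed. Every day is
#' logged and becomes an online training record.
#'
#' @param model A `growth_fit` (the forward model being tracked).
#' @param target Target morphology `c(hypocotyl_mm, stem_mm)`.
#' @param initial_recipe One-row recipe tibble — typically the
#'   inverse-design output ([design_recipe()]), whose `days` also sets
#'   `total_days`.
#' @param total_days Number of days to run.
#' @param params Twin parameters (the "real plants").
#' @param config A [controller_config()].
#' @param seed Integer seed for measurement noise and plant-to-plant
#'   variation.
#' @param adjust Apply adjustments? `FALSE` runs the same loop
#'   open-loop (for controller-usefulness comparisons).
#' @param role Twin role.
#' @param n_plants Number of seedlings in the controlled tray.
#' @return An object of class `"control_state"`: list with `log` (one
#'   row per day), `final` (cohort-mean true final morphology), `target`,
#'   `achieved_deviation` (relative to the target, per trait),
#'   `prediction_deviation` (relative to the model's final-day
#'   prediction, per trait — the quantity a cultivation validation
#'   compares against), `n_actions`, `config`.
#' @export
run_closed_loop <- function(model, target, initial_recipe, total_days,
                            params = twin_params(),
                            config = controller_config(), seed = 1,
                            adjust = TRUE,
                            role = c("rootstock", "scion"),
                            n_plants = 20) {
  role <- match.arg(role)
  target <- as_target(target)
  if (total_days < 1) abort("total_days must be >= 1")
  if (n_plants < 1) abort("n_plants must be >= 1")
  set.seed(seed)
  rate_factor <- pmax(rnorm(n_plants, 1, params$rate_cv), 0.5)
  role_factor <- if (role == "scion") params$scion_rate_factor else 1

  recipe <- light_recipe(initial_recipe$red_umol[1],
                         initial_recipe$blue_umol[1],
                         initial_recipe$photoperiod_h[1])
  H <- rep(params$hyp_init, n_plants)
  S <- rep(params$stem_init, n_plants)
  log <- NULL
  plant_log <- NULL
  n_actions <- 0L

  for (day in seq_len(total_days)) {
    for (i in seq_len(n_plants)) {
      state <- twin_step(params, H[i], S[i], recipe$red_umol,
                         recipe$blue_umol, recipe$photoperiod_h, day = day,
                         rate_scale = role_factor * rate_factor[i])
      H[i] <- state[["H"]]
      S[i] <- state[["S"]]
    }

    plant_h <- measure_with_noise(H, params$noise_hyp_mm)
    plant_s <- measure_with_noise(S, params$noise_stem_mm)
    measured <- tibble(
      hypocotyl_mm = mean(plant_h),
      stem_mm = mean(plant_s)
    )
    plant_log <- bind_rows(plant_log, tibble(
      day = day, plant = seq_len(n_plants),
      red_umol = recipe$red_umol, blue_umol = recipe$blue_umol,
      photoperiod_h = recipe$photoperiod_h,
      hypocotyl_mm = plant_h, stem_mm = plant_s
    ))
    predicted <- predict(model, tibble(
      red_umol = recipe$red_umol, blue_umol = recipe$blue_umol,
      photoperiod_h = recipe$photoperiod_h, day = day
    ))
    action <- decide_action(measured, predicted, config)
    acted <- adjust && day >= config$start_day &&
      action$triggered_by != "none"
    if (acted) n_actions <- n_actions + 1L

    log <- bind_rows(log, bind_cols(
      tibble(day = day),
      rename(recipe, red_umol = "red_umol"),
      tibble(predicted_hypocotyl_mm = predicted$hypocotyl_mm,
             predicted_stem_mm = predicted$stem_mm,
             measured_hypocotyl_mm = measured$hypocotyl_mm,
             measured_stem_mm = measured$stem_mm,
             true_hypocotyl_mm = mean(H), true_stem_mm = mean(S)),
      action
    ))
    if (acted) {
      recipe <- apply_action(recipe, action, config)
    }
  }

  final <- tibble(hypocotyl_mm = mean(H), stem_mm = mean(S))
  last <- log[nrow(log), ]
  structure(
    list(
      log = log, plant_log = plant_log, final = final, target = target,
      achieved_deviation = c(
        hypocotyl = abs(final$hypocotyl_mm - target[1]) / target[1],
        stem = abs(final$stem_mm - target[2]) / target[2]
      ),
      prediction_deviation = c(
        hypocotyl = abs(final$hypocotyl_mm - last$predicted_hypocotyl_mm) /
          last$predicted_hypocotyl_mm,
        stem = abs(final$stem_mm - last$predicted_stem_mm) /
          last$predicted_stem_mm
      ),
      n_actions = n_actions, config = config, role = role
    ),
    class = "control_state"
  )
}

#' @export
print.control_state <- function(x, ...) {
  cat("<control_state> ", nrow(x$log), " days, ", x$n_actions,
      " adjustments\n", sep = "")
  cat("  final: hypocotyl ", format(round(x$final$hypocotyl_mm, 2)),
      " mm (target ", x$target[1], ", deviation ",
      format(round(100 * x$achieved_deviation[["hypocotyl"]], 2)),
      "%), stem ", format(round(x$final$stem_mm, 3)),
      " mm (target ", x$target[2], ", deviation ",
      format(round(100 * x$achieved_deviation[["stem"]], 2)), "%)\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy control_state
tidy.control_state <- function(x, ...) x$log

#' @export
#' @method glance control_state
glance.control_state <- function(x, ...) {
  tibble(
    days = nrow(x$log), n_actions = x$n_actions,
    final_hypocotyl_mm = x$final$hypocotyl_mm,
    final_stem_mm = x$final$stem_mm,
    target_hypocotyl_mm = x$target[1], target_stem_mm = x$target[2],
    deviation_hypocotyl = x$achieved_deviation[["hypocotyl"]],
    deviation_stem = x$achieved_deviation[["stem"]],
    prediction_deviation_hypocotyl = x$prediction_deviation[["hypocotyl"]],
    prediction_deviation_stem = x$prediction_deviation[["stem"]]
  )
}

#' Convert a control log into online training records
#'
#' Every measured plant of every logged day becomes a growth record
#' (recipe, day, measured morphology) suitable for appending to the
#' training buffer and re-fitting the forward model; idempotent per
#' day. States logged without per-plant detail fall back to one
#' cohort-mean record per day.
#'
#' @param state A `control_state`.
#' @param treatment_id Label for the online records.
#' @return Growth-dataset tibble (possibly empty).
#' @export
accumulate_online <- function(state, treatment_id = "online") {
  if (is.null(state$log) || nrow(state$log) == 0) {
    return(tibble(
      treatment_id = character(), role = character(), replicate = integer(),
      day = integer(), red_umol = numeric(), blue_umol = numeric(),
      photoperiod_h = numeric(), hypocotyl_mm = numeric(),
      stem_mm = numeric()
    ))
  }
  if (!is.null(state$plant_log)) {
    return(
      state$plant_log %>%
        distinct(.data$day, .data$plant, .keep_all = TRUE) %>%
        mutate(treatment_id = treatment_id, role = state$role) %>%
        select("treatment_id", "role", replicate = "plant", "day",
               "red_umol", "blue_umol", "photoperiod_h",
               "hypocotyl_mm", "stem_mm")
    )
  }
  state$log %>%
    distinct(.data$day, .keep_all = TRUE) %>%
    mutate(treatment_id = treatment_id, role = state$role,
           replicate = 1L) %>%
    select("treatment_id", "role", "replicate", "day", "red_umol",
           "blue_umol", "photoperiod_h",
           hypocotyl_mm = "measured_hypocotyl_mm",
           stem_mm = "measured_stem_mm")
}

#' Validate a morphology target with the full closed-loop protocol
#'
#' Runs the complete deployment cycle for one target morphology:
#' inverse-design an initial recipe from the forward model; run a pilot
#' cultivation whose daily records are accumulated online; refit the
#' model on the design data plus the online records (which fills in the
#' day axis along the visited trajectory, where the original design only
#' samples five-day intervals); redesign the recipe with the refined
#' model; then run `n_replicates` independently seeded closed-loop
#' cultivations and report the achieved deviations.
#'
#' @param data The growth dataset the forward model is trained on.
#' @param target Target morphology `c(hypocotyl_mm, stem_mm)`.
#' @param spec Model specification for (re)fitting.
#' @param params Twin parameters.
#' @param config Controller configuration.
#' @param bounds,de_settings,error_threshold Passed to [design_recipe()].
#' @param n_replicates Number of evaluation cultivations.
#' @param seed Base seed; the pilot uses `seed`, replicate r uses
#'   `seed + r`.
#' @param n_plants Tray size per cultivation.
#' @param refine Number of pilot/refit/redesign cycles (0 evaluates the
#'   initial design directly).
#' @param support_threshold Trust-region radius passed to
#'   [design_recipe()].
#' @param history_free Drop recipe-transition treatments from the
#'   training data? A memoryless (recipe, day) feature map cannot
#'   distinguish treatments that share features but differ in light
#'   history, which biases inverse design toward unrealizable
#'   predictions.
#' @return A list of class `"target_validation"`: `recipe` and `days`
#'   (the deployed cultivation), `error` (model-predicted Euclidean
#'   distance to the target at deployment), `pilot_score` (measured
#'   distance in the calibration cultivation), `replicates` (tibble,
#'   one row per evaluation cultivation with final morphology and
#'   deviations), `model` (the online-refined fit), `solution` (the
#'   last evolutionary design), and `feasible`.
#' @export
validate_target <- function(data, target, spec = model_spec(),
                            params = twin_params(),
                            config = controller_config(),
                            bounds = search_bounds(),
                            de_settings = de_config(),
                            error_threshold = 0.3,
                            n_replicates = 20, seed = 1, n_plants = 20,
                            refine = 5, history_free = TRUE,
                            support_threshold = 0.03) {
  target <- as_target(target)
  train <- as_tibble(data)
  if (history_free) {
    # a memoryless (recipe, day) feature map is only well-posed for
    # treatments whose recipe never changed; transition treatments carry
    # history the features cannot express
    if ("constant_recipe" %in% names(train)) {
      train <- filter(train, .data$constant_recipe)
    } else if ("treatment_id" %in% names(train)) {
      constant <- train %>%
        group_by(.data$treatment_id) %>%
        summarise(n_recipes = dplyr::n_distinct(
          paste(.data$red_umol, .data$blue_umol, .data$photoperiod_h)
        ), .groups = "drop")
      keep <- constant$treatment_id[constant$n_recipes == 1]
      train <- filter(train, .data$treatment_id %in% keep)
    }
  }
  model <- fit_growth_model(train, spec)
  # the trust region is the physical design support: recipes the twin was
  # actually cultivated under; online pilot records refine the model's
  # day resolution but do not widen the region
  design_support <- train
  sol <- design_recipe(model, target, bounds, de_settings, error_threshold,
                       support = design_support,
                       support_threshold = support_threshold,
                       support_weight = 50)

  # Candidate recipes are verified by calibration cultivations: each
  # round pilots the current candidate open-loop for the full horizon,
  # reads the harvest day with the smallest measured distance to the
  # target off the pilot log, and keeps the best verified
  # (recipe, days) pair. The online records feed back into training, so
  # each refit resolves the day axis (and the local recipe
  # neighbourhood) where candidates actually grow.
  best <- NULL
  for (round in seq_len(refine)) {
    cand <- if (sol$feasible) sol$recipe else {
      light_recipe(sol$best[1], sol$best[2], sol$best[3])
    }
    pilot <- run_closed_loop(model, target, cand, bounds$days[2],
                             params = params, config = config,
                             seed = seed + 1000 * round, n_plants = n_plants,
                             adjust = FALSE)
    traj <- filter(pilot$log, .data$day >= bounds$days[1])
    dist <- sqrt((traj$measured_hypocotyl_mm - target[1])^2 +
                   (traj$measured_stem_mm - target[2])^2)
    if (is.null(best) || min(dist) < best$score) {
      best <- list(recipe = cand, days = traj$day[which.min(dist)],
                   score = min(dist))
    }
    online <- accumulate_online(pilot, treatment_id = paste0("online_", round))
    train <- bind_rows(train[, names(online)], online)
    model <- fit_growth_model(train, spec)
    sol <- design_recipe(model, target, bounds, de_settings, error_threshold,
                         support = design_support,
                         support_threshold = support_threshold,
                         support_weight = 50)
  }

  if (is.null(best)) {
    best <- if (sol$feasible) {
      list(recipe = sol$recipe, days = sol$days, score = sol$error)
    } else {
      list(recipe = light_recipe(sol$best[1], sol$best[2], sol$best[3]),
           days = round(sol$best[4]), score = sol$best_error)
    }
  }

  deploy_pred <- predict(model, tibble(
    red_umol = best$recipe$red_umol, blue_umol = best$recipe$blue_umol,
    photoperiod_h = best$recipe$photoperiod_h, day = best$days
  ))
  deploy_error <- sqrt((deploy_pred$hypocotyl_mm - target[1])^2 +
                         (deploy_pred$stem_mm - target[2])^2)

  replicates <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    st <- run_closed_loop(model, target, best$recipe, best$days,
                          params = params, config = config,
                          seed = seed + r, n_plants = n_plants)
    glance(st) %>% mutate(replicate = r, .before = 1)
  })
  structure(
    list(solution = sol, recipe = best$recipe, days = best$days,
         pilot_score = best$score, error = deploy_error,
         predicted = deploy_pred, replicates = replicates, model = model,
         feasible = deploy_error < error_threshold, target = target),
    class = "target_validation"
  )
}

#' @export
print.target_validation <- function(x, ...) {
  cat("<target_validation> target (", x$target[1], " mm, ", x$target[2],
      " mm): ", if (x$feasible) "feasible" else "infeasible",
      ", deployed ", x$days, " days\n", sep = "")
  if (nrow(x$replicates) > 0) {
    cat("  max deviation vs prediction: hypocotyl ",
        format(round(100 * max(x$replicates$prediction_deviation_hypocotyl), 2)),
        "%, stem ",
        format(round(100 * max(x$replicates$prediction_deviation_stem), 2)),
        "%\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method tidy target_validation
tidy.target_validation <- function(x, ...) x$replicates
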