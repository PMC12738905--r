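test_that("relative deviation handles the documented cases", {
  expect_equal(relative_deviation(50, 50), 0)
  expect_equal(relative_deviation(45, 50), 0.10)
  expect_equal(relative_deviation(3.36, 3.0), 0.12)
  expect_error(relative_deviation(1, 0), "positive")
})

test_that("adjustment directions follow the rule table exhaustively", {
  cfg <- controller_config()
  # magnitudes chosen to clear both the 10 % band and the absolute floors
  lvl <- list(short = 0.8, ok = 1, long = 1.2)
  for (hs in names(lvl)) {
    for (ss in names(lvl)) {
      meas <- tibble::tibble(hypocotyl_mm = 50 * lvl[[hs]],
                             stem_mm = 3 * lvl[[ss]])
      pred <- tibble::tibble(hypocotyl_mm = 50, stem_mm = 3)
      act <- decide_action(meas, pred, cfg)
      if (hs == "ok" && ss == "ok") {
        expect_equal(act$triggered_by, "none")
        expect_equal(act$red_ratio, "hold")
      } else if (hs == "short" && ss == "ok") {
        expect_equal(unlist(act[, 1:3]), c(
          red_ratio = "increase", intensity = "decrease",
          photoperiod = "decrease"
        ))
      } else if (hs == "long" && ss == "ok") {
        expect_equal(unlist(act[, 1:3]), c(
          red_ratio = "decrease", intensity = "increase",
          photoperiod = "increase"
        ))
      } else if (hs == "ok" && ss == "short") {
        expect_equal(unlist(act[, 1:3]), c(
          red_ratio = "decrease", intensity = "increase",
          photoperiod = "increase"
        ))
      } else if (hs == "ok" && ss == "long") {
        expect_equal(unlist(act[, 1:3]), c(
          red_ratio = "increase", intensity = "decrease",
          photoperiod = "decrease"
        ))
      } else {
        # both violated: hypocotyl rule drives ratio and photoperiod,
        # stem rule drives intensity
        expect_equal(act$triggered_by, "both")
        hyp_dir <- if (hs == "short") "increase" else "decrease"
        stem_int <- if (ss == "short") "increase" else "decrease"
        expect_equal(act$red_ratio, hyp_dir)
        expect_equal(act$photoperiod,
                     if (hs == "short") "decrease" else "increase")
        expect_equal(act$intensity, stem_int)
      }
    }
  }
})

test_that("no action is emitted inside the deadband or below the floors", {
  cfg <- controller_config()
  set.seed(8)
  for (i in 1:50) {
    p <- tibble::tibble(hypocotyl_mm = runif(1, 30, 80),
                        stem_mm = runif(1, 2, 4))
    m <- p * (1 + runif(2, -0.09, 0.09))
    act <- decide_action(m, p, cfg)
    expect_equal(act$triggered_by, "none")
  }
  # large relative but tiny absolute deviation: still no action
  act <- decide_action(tibble::tibble(hypocotyl_mm = 5.9, stem_mm = 0.12),
                       tibble::tibble(hypocotyl_mm = 5, stem_mm = 0.1), cfg)
  expect_equal(act$triggered_by, "none")
})

test_that("applying actions conserves flux on ratio moves and clips at bounds", {
  cfg <- controller_config()
  rec <- light_recipe(100, 100, 12)

  hold <- tibble::tibble(red_ratio = "hold", intensity = "hold",
                         photoperiod = "hold", triggered_by = "none",
                         deviation_hypocotyl = 0, deviation_stem = 0)
  expect_equal(apply_action(rec, hold, cfg), rec)

  ratio_up <- hold
  ratio_up$red_ratio <- "increase"
  out <- apply_action(rec, ratio_up, cfg)
  expect_equal(out$red_umol + out$blue_umol,
               rec$red_umol + rec$blue_umol, tolerance = 1e-9)
  expect_gt(out$red_umol, rec$red_umol)

  # intensity decrease at the lower bound leaves intensity unchanged
  low <- light_recipe(50, 50, 10)
  dec <- hold
  dec$intensity <- "decrease"
  dec$photoperiod <- "decrease"
  out2 <- apply_action(low, dec, cfg)
  expect_equal(out2$red_umol + out2$blue_umol, 100)
  expect_equal(out2$photoperiod_h, 10)
})

test_that("a loop against the model's own generating process never acts", {
  params <- twin_params(noise_hyp_mm = 0, noise_stem_mm = 0, rate_cv = 0)
  oracle <- twin_oracle_model(params)
  st <- run_closed_loop(oracle, c(50, 3), light_recipe(125, 125, 12),
                        total_days = 15, params = params, seed = 1,
                        n_plants = 2)
  expect_equal(st$n_actions, 0)
  expect_true(all(st$log$triggered_by == "none"))
  expect_equal(st$prediction_deviation[["hypocotyl"]], 0, tolerance = 1e-9)
  expect_equal(st$prediction_deviation[["stem"]], 0, tolerance = 1e-9)
})

test_that("recipes stay within bounds throughout the loop", {
  params <- twin_params()
  oracle <- twin_oracle_model(twin_params(hyp_rate = 0.30))  # mismatched
  st <- run_closed_loop(oracle, c(50, 3), light_recipe(55, 55, 10),
                        total_days = 25, params = params, seed = 2)
  b <- search_bounds()
  expect_true(all(st$log$red_umol >= b$red[1] - 1e-9))
  expect_true(all(st$log$blue_umol >= b$blue[1] - 1e-9))
  expect_true(all(st$log$photoperiod_h >= b$photoperiod[1] - 1e-9))
  expect_true(all(st$log$photoperiod_h <= b$photoperiod[2] + 1e-9))
  expect_true(all(diff(st$log$day) > 0))
})

test_that("closed-loop control beats open loop when tracking a growth schedule", {
  # reference model: a planned hypocotyl schedule insensitive to the
  # recipe; the twin under the initial recipe elongates faster than the
  # plan, so the controller must suppress elongation. Stem control is
  # silenced through its absolute floor to isolate the hypocotyl channel.
  plan <- linear_growth_fit(c(4, 0, 0, 0, 2.2), c(0.25, 0, 0, 0, 0.15))
  cfg <- controller_config(min_abs_stem_mm = 99)
  params <- twin_params(noise_hyp_mm = 0.2, noise_stem_mm = 0.02)
  on <- run_closed_loop(plan, c(48, 3), light_recipe(100, 100, 12),
                        total_days = 20, params = params, config = cfg,
                        seed = 3, adjust = TRUE)
  off <- run_closed_loop(plan, c(48, 3), light_recipe(100, 100, 12),
                         total_days = 20, params = params, config = cfg,
                         seed = 3, adjust = FALSE)
  expect_gt(on$n_actions, 0)
  expect_lt(on$prediction_deviation[["hypocotyl"]],
            off$prediction_deviation[["hypocotyl"]])
})

test_that("online accumulation produces well-formed training increments", {
  params <- twin_params()
  oracle <- twin_oracle_model(params)
  st <- run_closed_loop(oracle, c(50, 3), light_recipe(125, 125, 12),
                        total_days = 25, params = params, seed = 4,
                        n_plants = 1)
  inc <- accumulate_online(st)
  expect_equal(nrow(inc), 25)
  expect_setequal(
    names(inc),
    c("treatment_id", "role", "replicate", "day", "red_umol", "blue_umol",
      "photoperiod_h", "hypocotyl_mm", "stem_mm")
  )
  # idempotent per day, and one record per measured plant
  expect_equal(nrow(accumulate_online(st)), dplyr::n_distinct(st$log$day))
  st20 <- run_closed_loop(oracle, c(50, 3), light_recipe(125, 125, 12),
                          total_days = 10, params = params, seed = 4,
                          n_plants = 20)
  expect_equal(nrow(accumulate_online(st20)), 10 * 20)

  # empty log yields an empty increment
  empty <- structure(list(log = NULL, role = "rootstock"),
                     class = "control_state")
  expect_equal(nrow(accumulate_online(empty)), 0)

  # refitting on original + increment keeps the split leak-free
  d <- small_design_dataset()
  combined <- dplyr::bind_rows(d[, names(inc)], inc)
  sp <- time_series_split(combined)
  expect_length(intersect(unique(sp$train$day), unique(sp$test$day)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(combined))
})
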