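test_that("default registry carries the grafting-machine configuration", {
  reg <- indicator_registry()
  expect_equal(nrow(reg), 12)
  expect_setequal(unique(reg$kind), c(
    "positive", "negative", "interval_target_value", "interval_target_range"
  ))

  hyp <- reg[reg$indicator == "hypocotyl_length", ]
  expect_equal(hyp$kind, "interval_target_value")
  expect_equal(c(hyp$range_min, hyp$range_max, hyp$target), c(0, 150, 50))

  stem <- reg[reg$indicator == "stem_diameter", ]
  expect_equal(stem$kind, "interval_target_range")
  expect_equal(c(stem$range_min, stem$range_max), c(0, 5))
  expect_equal(c(stem$target_min, stem$target_max), c(2.7, 3.3))

  shear <- reg[reg$indicator == "shear_strength", ]
  expect_equal(shear$kind, "negative")
  expect_equal(c(shear$range_min, shear$range_max), c(0, 5))

  moist <- reg[reg$indicator == "moisture_content", ]
  expect_equal(c(moist$target_min, moist$target_max),
               c(moist$range_min, moist$range_max))
})

test_that("registry validation rejects malformed configurations", {
  reg <- indicator_registry()
  bad <- reg
  bad$range_min[1] <- bad$range_max[1]
  expect_error(validate_registry(bad), "range_min")

  bad <- reg
  bad$target[bad$indicator == "hypocotyl_length"] <- 200
  expect_error(validate_registry(bad), "target")

  bad <- reg
  bad$kind[1] <- "mystery"
  expect_error(validate_registry(bad), "kind")
})

test_that("standardizers reproduce the closed-form values", {
  reg <- indicator_registry()
  spec_of <- function(name) reg[reg$indicator == name, ]

  # positive: min-max
  fw <- spec_of("fresh_weight")
  expect_equal(standardize_positive(0, fw), 0)
  expect_equal(standardize_positive(5, fw), 1)
  expect_equal(standardize_positive(2.5, fw), 0.5)

  # negative: reversed min-max
  ph <- spec_of("plant_height")
  expect_equal(standardize_negative(250, ph), 0)
  expect_equal(standardize_negative(0, ph), 1)
  expect_equal(standardize_negative(100, ph), 0.6)

  # target value: distance from the target, scaled by the worse side
  hyp <- spec_of("hypocotyl_length")
  expect_equal(standardize_target_value(50, hyp), 1)
  expect_equal(standardize_target_value(150, hyp), 0)
  expect_equal(standardize_target_value(0, hyp), 0.5)

  # target range: plateau and ramps
  stem <- spec_of("stem_diameter")
  expect_equal(standardize_target_range(3.0, stem), 1)
  expect_equal(standardize_target_range(1.35, stem), 0.5)
  expect_equal(standardize_target_range(2.7, stem), 1)
  expect_equal(standardize_target_range(5, stem), 0)

  # collapsed ramps: target range equals admissible range
  moist <- spec_of("moisture_content")
  expect_equal(standardize_target_range(90, moist), 1)
  expect_equal(standardize_target_range(85, moist), 1)
  expect_equal(standardize_target_range(80, moist), 0)
})

test_that("out-of-range values error for admissibility-bounded kinds", {
  reg <- indicator_registry()
  expect_error(
    standardize_positive(6, reg[reg$indicator == "fresh_weight", ]),
    "fresh_weight"
  )
  expect_error(
    standardize_target_value(151, reg[reg$indicator == "hypocotyl_length", ]),
    "hypocotyl_length"
  )
  # target-range kind scores 0 instead of erroring
  expect_equal(
    standardize_target_range(6, reg[reg$indicator == "stem_diameter", ]), 0
  )
})

test_that("dispatching standardizer agrees with an independent piecewise oracle", {
  reg <- indicator_registry()
  # direct re-implementation of the four formulas, no shared code path
  oracle <- function(v, s) {
    if (s$kind == "positive") {
      (v - s$range_min) / (s$range_max - s$range_min)
    } else if (s$kind == "negative") {
      (s$range_max - v) / (s$range_max - s$range_min)
    } else if (s$kind == "interval_target_value") {
      1 - abs(v - s$target) / max(s$target - s$range_min,
                                  s$range_max - s$target)
    } else {
      if (v >= s$target_min && v <= s$target_max) 1
      else if (v >= s$range_min && v < s$target_min) {
        (v - s$range_min) / (s$target_min - s$range_min)
      } else if (v > s$target_max && v <= s$range_max) {
        (s$range_max - v) / (s$range_max - s$target_max)
      } else 0
    }
  }
  set.seed(11)
  for (rep in 1:1000) {
    i <- sample(nrow(reg), 1)
    s <- as.list(reg[i, ])
    v <- runif(1, s$range_min, s$range_max)
    got <- standardize_value(v, reg[i, ])
    expect_equal(got, oracle(v, s), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("comprehensive score is the weighted sum with maximum 1", {
  reg <- indicator_registry()
  w <- uniform_weights(reg)
  ones <- setNames(rep(1, 12), reg$indicator)
  expect_identical(comprehensive_score(ones, w), 1)
  expect_identical(comprehensive_score(ones * 0, w), 0)
  expect_equal(comprehensive_score(ones * 0.5, w), 0.5)

  # linearity and ordering invariance
  set.seed(3)
  t1 <- setNames(runif(12), reg$indicator)
  t2 <- setNames(runif(12), reg$indicator)
  expect_equal(
    comprehensive_score(0.3 * t1 + 0.7 * t2, w),
    0.3 * comprehensive_score(t1, w) + 0.7 * comprehensive_score(t2, w)
  )
  shuffled <- t1[sample(names(t1))]
  expect_equal(comprehensive_score(shuffled, w), comprehensive_score(t1, w))

  expect_error(comprehensive_score(t1[-1], w), "missing")
})

test_that("cohort scoring averages per-seedling scores and ranks targets", {
  reg <- tiny_registry()
  w <- uniform_weights(reg)
  rec <- tibble::tibble(len = c(40, 40), mass = c(5, 5), defect = c(2, 2))
  out <- score_cohort(rec, reg, w)
  single <- score_seedlings(rec[1, ], reg, w)$score
  expect_equal(out$mean_score, single)
  expect_equal(out$n, 2)

  two <- tibble::tibble(len = c(40, 0), mass = c(10, 0), defect = c(0, 4))
  out2 <- score_cohort(two, reg, w)
  scored <- attr(out2, "scores")
  expect_equal(out2$mean_score, mean(scored$score))

  expect_error(score_cohort(rec[0, ], reg, w), "empty")

  # hypocotyls near the 50 mm target outscore hypocotyls near 20 mm
  full <- indicator_registry()
  base <- setNames(as.list(rep(1, 12)), full$indicator)
  mk <- function(h) {
    r <- tibble::as_tibble(base)
    r$hypocotyl_length <- h
    r$stem_diameter <- 3
    r$moisture_content <- 90
    r$plant_height <- 100
    r$fresh_weight <- 2.5
    r$shoot_dry_weight <- 0.25
    r$root_dry_weight <- 0.25
    r$seedling_strength_index <- 0.5
    r$radial_compression_force <- 25
    r$axial_compression_force <- 7
    r$bending_strength <- 2.5
    r$shear_strength <- 2.5
    r
  }
  good <- score_cohort(dplyr::bind_rows(lapply(c(48, 50, 52), mk)))
  poor <- score_cohort(dplyr::bind_rows(lapply(c(18, 20, 22), mk)))
  expect_gt(good$mean_score, poor$mean_score)
})
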