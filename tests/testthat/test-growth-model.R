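test_that("time-series split partitions by sampling day", {
  d <- small_design_dataset()
  sp <- time_series_split(d)
  expect_setequal(unique(sp$train$day), c(5, 10, 15, 20, 25))
  expect_setequal(unique(sp$test$day), 30)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d))
  expect_length(intersect(unique(sp$train$day), unique(sp$test$day)), 0)

  one_day <- d[d$day == 5, ]
  expect_error(time_series_split(one_day), "distinct day")

  # single-treatment data follows the same rule
  sp1 <- time_series_split(d[d$treatment_id == "I_200", ])
  expect_setequal(unique(sp1$test$day), 30)
})

test_that("augmentation appends bounded jitter and keeps originals", {
  d <- small_design_dataset()
  sp <- time_series_split(d)

  aug0 <- augment_training(sp$train, noise_level = 0, perturbation = 0, seed = 1)
  expect_equal(nrow(aug0), 2 * nrow(sp$train))
  expect_equal(aug0$hypocotyl_mm[-seq_len(nrow(sp$train))],
               sp$train$hypocotyl_mm)

  aug <- augment_training(sp$train, seed = 1)
  expect_equal(nrow(aug), 2 * nrow(sp$train))
  originals <- aug[seq_len(nrow(sp$train)), ]
  expect_equal(originals$hypocotyl_mm, sp$train$hypocotyl_mm)
  expect_equal(originals$day, as.numeric(sp$train$day))
  jit <- aug[-seq_len(nrow(sp$train)), ]
  for (f in c("red_umol", "blue_umol", "photoperiod_h", "day")) {
    ratio <- jit[[f]] / sp$train[[f]]
    ratio <- ratio[is.finite(ratio)]
    expect_true(all(ratio >= 0.95 - 1e-9 & ratio <= 1.05 + 1e-9))
  }
})

test_that("linear model attains a perfect fit on affine data", {
  set.seed(4)
  n <- 60
  d <- tibble::tibble(
    red_umol = runif(n, 50, 250), blue_umol = runif(n, 50, 250),
    photoperiod_h = runif(n, 10, 18), day = sample(5:30, n, replace = TRUE)
  )
  d$hypocotyl_mm <- 2 + 0.1 * d$red_umol - 0.05 * d$blue_umol + 1.5 * d$day
  d$stem_mm <- 0.2 + 0.002 * d$blue_umol + 0.08 * d$day

  fit <- fit_growth_model(d, model_spec("linear"))
  ev <- evaluate_growth_model(fit, d)
  expect_equal(ev$metrics$r2, c(1, 1), tolerance = 1e-9)
  expect_lt(max(ev$metrics$mae), 1e-9)
})

test_that("all model families fit and predict deterministically", {
  d <- small_design_dataset()
  sp <- time_series_split(d)
  for (algo in c("linear", "ridge", "random_forest", "gradient_boosting")) {
    f1 <- fit_growth_model(sp$train, model_spec(algo))
    f2 <- fit_growth_model(sp$train, model_spec(algo))
    p1 <- predict(f1, sp$test)
    p2 <- predict(f2, sp$test)
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1$hypocotyl_mm)))
  }
})

test_that("constant targets are handled by the linear families", {
  d <- tibble::tibble(
    red_umol = runif(10, 50, 250), blue_umol = runif(10, 50, 250),
    photoperiod_h = 12, day = 1:10,
    hypocotyl_mm = 42, stem_mm = 3
  )
  fit <- fit_growth_model(d, model_spec("linear"))
  p <- predict(fit, d)
  expect_equal(p$hypocotyl_mm, rep(42, 10))
})

test_that("evaluation metrics match hand-computed values", {
  # 3-point fixture with known residuals via an exact linear stub
  stub <- day_monotone_fit(h_per_day = 2, s_per_day = 0.1)
  test <- tibble::tibble(
    red_umol = 0, blue_umol = 0, photoperiod_h = 0, day = c(1, 2, 3),
    hypocotyl_mm = c(7, 8, 8),   # predictions: 6, 8, 10
    stem_mm = c(0.35, 0.45, 0.55)  # predictions exact
  )
  ev <- evaluate_growth_model(stub, test)
  m <- ev$metrics[ev$metrics$target == "hypocotyl_mm", ]
  expect_equal(m$mae, mean(abs(c(1, 0, -2))))
  expect_equal(m$mse, mean(c(1, 0, 4)))
  expect_equal(m$rmse, sqrt(m$mse))
  ss_tot <- sum((test$hypocotyl_mm - mean(test$hypocotyl_mm))^2)
  expect_equal(m$r2, 1 - 5 / ss_tot)

  s <- ev$metrics[ev$metrics$target == "stem_mm", ]
  expect_equal(s$mae, 0)
  expect_equal(s$r2, 1)

  # identities
  expect_true(all(ev$metrics$mae <= ev$metrics$rmse + 1e-12))
  expect_true(all(ev$metrics$r2 <= 1))

  # zero-variance observations
  flat <- test
  flat$hypocotyl_mm <- 8
  expect_warning(ev2 <- evaluate_growth_model(stub, flat), "zero-variance")
  expect_true(is.nan(ev2$metrics$r2[1]))
})

test_that("comprehensive R-squared is the weighted mean of the outputs", {
  expect_equal(comprehensive_r2(0.9305, 0.9363), 0.9334)
  expect_equal(comprehensive_r2(0.9048, 0.9457), 0.92525)
  expect_equal(comprehensive_r2(0.7, 0.9, c(1, 0)), 0.7)
  expect_error(comprehensive_r2(0.9, 0.9, c(0.6, 0.6)), "summing to 1")
})

test_that("relative improvement reproduces reported optimization gains", {
  expect_equal(round(relative_improvement(3.4375, 3.2628), 2), 5.08)
  expect_equal(signif(relative_improvement(24.5805, 20.7465), 3), 15.6)
  expect_equal(relative_improvement(7, 7), 0)
  expect_error(relative_improvement(0, 1), "positive")
  expect_error(relative_improvement(-2, 1), "positive")
})

test_that("model comparison ranks gradient boosting at or above linear", {
  d <- small_design_dataset()
  tab <- compare_models(d, list(model_spec("gradient_boosting"),
                                model_spec("linear")))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rank, 1:2)
  gb <- tab$comprehensive_r2[tab$algorithm == "gradient_boosting"]
  lin <- tab$comprehensive_r2[tab$algorithm == "linear"]
  expect_gte(gb, lin)

  one <- compare_models(d, list(model_spec("linear")))
  expect_equal(nrow(one), 1)

  tab2 <- compare_models(d, list(model_spec("gradient_boosting"),
                                 model_spec("linear")))
  expect_equal(tab$comprehensive_r2, tab2$comprehensive_r2)
})

test_that("fitted models round-trip through the archive format", {
  d <- small_design_dataset()
  sp <- time_series_split(d)
  for (algo in c("linear", "gradient_boosting")) {
    fit <- fit_growth_model(sp$train, model_spec(algo))
    path <- withr::local_tempfile(fileext = ".rds")
    save_growth_model(fit, path)
    reloaded <- load_growth_model(path)
    expect_equal(predict(reloaded, sp$test), predict(fit, sp$test))
    expect_equal(reloaded$spec$algorithm, algo)
  }
  suppressWarnings(
    expect_error(load_growth_model(withr::local_tempfile(fileext = ".rds")))
  )
})
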