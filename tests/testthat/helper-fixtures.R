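# shared fixtures: tiny registries, hand-built linear "growth models"
# whose predictions are exact affine functions of the features, and a
# twin-oracle model that predicts the noiseless twin trajectory

tiny_registry <- function() {
  validate_registry(tibble::tribble(
    ~indicator, ~kind,                   ~range_min, ~range_max, ~target, ~target_min, ~target_max, ~unit,
    "len",      "interval_target_value", 0,          100,        40,      NA,          NA,          "mm",
    "mass",     "positive",              0,          10,         NA,      NA,          NA,          "g",
    "defect",   "negative",              0,          4,          NA,      NA,          NA,          "-"
  ))
}

# growth_fit whose two outputs are affine in (red, blue, photoperiod, day)
linear_growth_fit <- function(beta_h, beta_s) {
  structure(
    list(
      spec = model_spec("linear"),
      fits = list(
        hypocotyl_mm = list(type = "ridge", beta = beta_h),
        stem_mm = list(type = "ridge", beta = beta_s)
      ),
      features = c("red_umol", "blue_umol", "photoperiod_h", "day"),
      targets = c("hypocotyl_mm", "stem_mm"),
      n_train = 0L, train_time_s = 0
    ),
    class = "growth_fit"
  )
}

# day-monotone stub: outputs depend on day only, strictly increasing
day_monotone_fit <- function(h_per_day = 2, s_per_day = 0.1) {
  linear_growth_fit(c(4, 0, 0, 0, h_per_day), c(0.25, 0, 0, 0, s_per_day))
}

# model that predicts the noiseless twin under the queried constant
# recipe, grown from emergence to the queried day
twin_oracle_model <- function(params = twin_params()) {
  structure(list(params = params), class = "twin_oracle_model")
}

predict.twin_oracle_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  out <- purrr::map_dfr(seq_len(nrow(newdata)), function(i) {
    row <- newdata[i, ]
    traj <- simulate_trajectory(
      light_recipe(row$red_umol, row$blue_umol, row$photoperiod_h),
      days = max(ceiling(row$day), 1), params = object$params,
      noise = FALSE
    )
    d <- round(row$day)
    tibble::tibble(hypocotyl_mm = traj$true_hypocotyl_mm[d + 1],
                   stem_mm = traj$true_stem_mm[d + 1])
  })
  out
}
registerS3method("predict", "twin_oracle_model", predict.twin_oracle_model)

# small shared twin dataset (computed once per test run)
small_design_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_design_dataset(n_per_treatment = 2, seed = 7)
    }
    cache
  }
})
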