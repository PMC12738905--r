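#' Time-series train/test split by sampling day
#'
#' Splits a growth dataset so the model is evaluated on later sampling
#' occasions than it was trained on: the distinct `day` values are
#' sorted, the first `ceiling(train_fraction * K)` of the K days form the
#' training set and the remaining days the test set. No day appears in
#' both. With the standard six sampling days (5, 10, ..., 30) and the
#' default 0.8 fraction, days 5--25 train and day 30 tests.
#'
#' @param data Growth dataset with a `day` column.
#' @param train_fraction Fraction of distinct days assigned to training.
#' @return A list with tibbles `train` and `test`.
#' @export
time_series_split <- function(data, train_fraction = 0.8) {
  data <- as_tibble(data)
  days <- sort(unique(data$day))
  if (length(days) < 2) abort("need at least 2 distinct day values to split")
  n_train <- ceiling(train_fraction * length(days))
  n_train <- min(max(n_train, 1), length(days) - 1)
  train_days <- days[seq_len(n_train)]
  list(
    train = filter(data, .data$day %in% train_days),
    test = filter(data, !.data$day %in% train_days)
  )
}

#' Augment a training set with jittered copies
#'
#' Appends to the training set one perturbed copy of every record:
#' targets receive Gaussian noise with standard deviation
#' `noise_level` times the per-target standard deviation (dimensionless
#' scaling, robust to units), and features are multiplied by independent
#' `1 + U(-perturbation, +perturbation)` factors. Originals are kept, so
#' the output has twice the rows. Augmentation is a training-set
#' operation only — never apply it to the test set.
#'
#' @param train Training tibble with feature and target columns.
#' @param noise_level Target noise as a fraction of each target's sd.
#' @param perturbation Half-width of the multiplicative feature jitter.
#' @param seed Integer seed.
#' @param features,targets Column names to perturb.
#' @return Tibble with `2 * nrow(train)` rows.
#' @export
augment_training <- function(train, noise_level = 0.01, perturbation = 0.05,
                             seed = 42,
                             features = c("red_umol", "blue_umol",
                                          "photoperiod_h", "day"),
                             targets = c("hypocotyl_mm", "stem_mm")) {
  if (nrow(train) == 0) abort("training set is empty")
  set.seed(seed)
  jit <- train
  for (f in features) {
    jit[[f]] <- jit[[f]] * (1 + runif(nrow(jit), -perturbation, perturbation))
  }
  for (y in targets) {
    s <- sd(train[[y]])
    if (!is.finite(s)) s <- 0
    jit[[y]] <- jit[[y]] + rnorm(nrow(jit), 0, noise_level * s)
  }
  bind_rows(train, jit)
}
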