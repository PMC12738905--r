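#' Objective weights by the entropy method
#'
#' Entropy weighting is driven entirely by data dispersion: the more
#' dispersed an indicator is across seedlings (the lower its entropy
#' share), the more discriminating it is and the higher its weight.
#' Inputs are standardized values in \[0, 1\] so directions and units are
#' already unified; pass raw measurements through
#' [standardize_measurements()] first (or let this function do it by
#' supplying a registry).
#'
#' For a matrix of n records and m indicators the canonical chain is
#' `p_ij = x_ij / sum_i x_ij`, `e_j = -(1/ln n) * sum_i p_ij ln p_ij`
#' (with `0 ln 0 := 0`), divergence `d_j = 1 - e_j`, and
#' `w_j = d_j / sum_j d_j`.
#'
#' @param data Data frame of measurements (rows = seedlings). Columns not
#'   in the registry are ignored.
#' @param registry Indicator registry used to standardize and to select
#'   columns; set to `NULL` if `data` is already standardized to \[0, 1\].
#' @return A weight tibble with method `"entropy"`.
#' @export
entropy_weights <- function(data, registry = indicator_registry()) {
  if (!is.null(registry)) {
    data <- standardize_measurements(data, registry)
    data <- data[, intersect(registry$indicator, names(data)), drop = FALSE]
  } else {
    data <- as_tibble(data)[, vapply(data, is.numeric, logical(1)), drop = FALSE]
  }
  X <- as.matrix(data)
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2) abort("entropy weights need at least 2 records")
  if (any(!is.finite(X)) || any(X < 0)) {
    abort("entropy weights need finite non-negative standardized values")
  }
  colsum <- colSums(X)
  if (any(colsum == 0)) {
    abort(paste0("all-zero indicator column(s): ",
                 paste(colnames(X)[colsum == 0], collapse = ", ")))
  }
  P <- sweep(X, 2, colsum, "/")
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  e <- -colSums(plogp) / log(n)
  d <- 1 - e
  if (sum(d) <= 0) {
    # every column perfectly uniform: no dispersion signal, fall back to
    # equal weights (the limit of the formula as dispersion -> 0)
    w <- rep(1 / m, m)
  } else {
    w <- d / sum(d)
  }
  weight_vector(colnames(X), w, method = "entropy")
}
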