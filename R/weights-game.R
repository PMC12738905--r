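#' Game-theoretic combination of weight vectors
#'
#' Blends L weight vectors (e.g. subjective AHP and objective entropy
#' weights) into one compromise vector `c' = sum_k alpha'_k c_k`. The
#' coefficients minimize the total squared deviation of the combination
#' from every input vector,
#' `sum_i || sum_k alpha_k c_k - c_i ||^2`,
#' whose first-order condition is the Gram linear system
#' `G alpha = diag(G)` with `G[i, k] = c_i . c_k`. The solved
#' coefficients are normalized to sum 1 and the combination re-assembled
#' from the normalized coefficients.
#'
#' A singular Gram system (collinear inputs) is resolved by the
#' least-squares pseudo-solution with a warning. Negative combined
#' weights can arise from the unconstrained solve when inputs disagree
#' strongly; because weights must stay interpretable, this errors unless
#' `nonneg = TRUE`, which instead minimizes the same deviation objective
#' under `alpha >= 0`.
#'
#' @param inputs List of weight tibbles sharing the same indicators (see
#'   [weight_vector()]); order of indicators may differ, they are aligned
#'   on the first input.
#' @param nonneg If `TRUE`, solve the deviation objective under
#'   non-negativity instead of erroring on negative combined weights.
#' @return An object of class `"game_combination"`: list with `inputs`,
#'   `gram`, `alpha_raw`, `alpha_norm`, and `weights` (the combined weight
#'   tibble, method `"combined"`).
#' @examples
#' a <- weight_vector(c("x", "y"), c(0.6, 0.4), "ahp")
#' b <- weight_vector(c("x", "y"), c(0.2, 0.8), "entropy")
#' game_combination(list(a, b))$weights
#' @export
game_combination <- function(inputs, nonneg = FALSE) {
  if (!is.list(inputs) || length(inputs) < 1) {
    abort("inputs must be a non-empty list of weight tibbles")
  }
  walk(inputs, check_weights)
  labels <- inputs[[1]]$indicator
  C <- vapply(inputs, function(w) {
    if (!setequal(w$indicator, labels)) {
      abort("all input weight vectors must share the same indicators")
    }
    w$weight[match(labels, w$indicator)]
  }, numeric(length(labels)))
  C <- matrix(C, nrow = length(labels))  # m x L, columns are c_k
  L <- ncol(C)

  G <- crossprod(C)                      # G[i, k] = c_i . c_k
  b <- diag(G)
  alpha <- tryCatch(
    solve(G, b),
    error = function(e) {
      warn("Gram system is singular (collinear inputs); using least-squares pseudo-solution")
      as.numeric(qr.coef(qr(G, LAPACK = TRUE), b))
    }
  )
  alpha[is.na(alpha)] <- 0

  if (sum(alpha) <= 0) {
    abort("sum of combination coefficients is not positive; combination undefined")
  }
  alpha_norm <- alpha / sum(alpha)
  combined <- as.numeric(C %*% alpha_norm)

  if (any(combined < -1e-12)) {
    if (!nonneg) {
      abort(paste0(
        "combined weights are negative for: ",
        paste(labels[combined < 0], collapse = ", "),
        "; inputs disagree too strongly for an interpretable unconstrained ",
        "combination (retry with nonneg = TRUE)"
      ))
    }
    fit <- optim(
      par = rep(1 / L, L),
      fn = function(a) deviation_objective(a, C),
      method = "L-BFGS-B", lower = rep(0, L)
    )
    alpha <- fit$par
    if (sum(alpha) <= 0) abort("non-negative combination degenerated to zero")
    alpha_norm <- alpha / sum(alpha)
    combined <- as.numeric(C %*% alpha_norm)
  }
  combined <- pmax(combined, 0)
  combined <- combined / sum(combined)

  structure(
    list(
      inputs = inputs,
      gram = G,
      alpha_raw = alpha,
      alpha_norm = alpha_norm,
      weights = weight_vector(labels, combined, method = "combined")
    ),
    class = "game_combination"
  )
}

# total squared deviation of the alpha-combination from every input column
deviation_objective <- function(alpha, C) {
  combined <- as.numeric(C %*% alpha)
  sum(apply(C, 2, function(ci) sum((combined - ci)^2)))
}

#' @export
print.game_combination <- function(x, ...) {
  cat("Game-theoretic combination of", length(x$inputs), "weight vectors\n")
  cat("alpha (normalized):", paste(format(round(x$alpha_norm, 4)), collapse = ", "), "\n")
  print(x$weights)
  invisible(x)
}

#' @export
#' @method tidy game_combination
tidy.game_combination <- function(x, ...) x$weights

#' @export
#' @method glance game_combination
glance.game_combination <- function(x, ...) {
  tibble(
    n_inputs = length(x$inputs),
    alpha_sum_raw = sum(x$alpha_raw),
    objective = deviation_objective(
      x$alpha_norm,
      vapply(x$inputs, function(w) {
        w$weight[match(x$weights$indicator, w$indicator)]
      }, numeric(nrow(x$weights)))
    )
  )
}

#' Combined subjective-objective weights in one call
#'
#' Convenience pipeline: AHP weights from a judgment matrix, entropy
#' weights from a measurement table, then the game-theoretic combination
#' of the two.
#'
#' @param J Judgment matrix over the registry's indicators.
#' @param data Measurement table for the entropy weights.
#' @param registry Indicator registry.
#' @param nonneg Passed to [game_combination()].
#' @return The combined weight tibble (method `"combined"`). The full
#'   [game_combination()] object is attached as attribute
#'   `"combination"`, the AHP consistency report as `"ahp"`.
#' @export
combined_weights <- function(J, data, registry = indicator_registry(),
                             nonneg = FALSE) {
  ahp <- ahp_weights(J, labels = rownames(J))
  ent <- entropy_weights(data, registry)
  comb <- game_combination(list(ahp$weights, ent), nonneg = nonneg)
  out <- comb$weights
  attr(out, "combination") <- comb
  attr(out, "ahp") <- ahp
  out
}
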