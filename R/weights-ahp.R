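#' Subjective weights by the Analytic Hierarchy Process
#'
#' Computes AHP weights from a pairwise judgment matrix on Saaty's 1--9
#' scale. The weight vector is the principal right eigenvector of the
#' matrix (power iteration), normalized to sum 1. Consistency is checked
#' with the consistency index `CI = (lambda_max - n) / (n - 1)` and the
#' consistency ratio `CR = CI / RI(n)` against Saaty's random-index table;
#' `CR >= 0.1` flags the matrix as inconsistent (a warning, not an error —
#' the caller decides whether to re-elicit judgments).
#'
#' @param J Square numeric matrix of pairwise judgments with unit diagonal
#'   and reciprocal symmetry (`J[j, i] = 1 / J[i, j]`), entries in
#'   \[1/9, 9\]. Dimnames, if present, provide the indicator labels.
#' @param labels Optional character vector of indicator names overriding
#'   the dimnames.
#' @return A list of class `"ahp_weights"` with elements `weights` (a
#'   weight tibble, method `"ahp"`), `lambda_max`, `ci`, `cr` and
#'   `consistent` (`CR < 0.1`).
#' @examples
#' J <- matrix(c(1, 3, 5, 1/3, 1, 3, 1/5, 1/3, 1), 3, 3, byrow = TRUE)
#' ahp_weights(J, labels = c("a", "b", "c"))
#' @export
ahp_weights <- function(J, labels = NULL) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (n != ncol(J) || n < 2 || n > 15) {
    abort("judgment matrix must be square with 2 <= n <= 15")
  }
  if (is.null(labels)) {
    labels <- rownames(J) %||% paste0("indicator_", seq_len(n))
  }
  validate_judgment_matrix(J)

  # principal right eigenvector by power iteration
  w <- rep(1 / n, n)
  for (iter in 1:500) {
    w_new <- as.numeric(J %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-13) {
      w <- w_new
      break
    }
    w <- w_new
  }
  lambda_max <- mean(as.numeric(J %*% w) / w)
  ci <- (lambda_max - n) / (n - 1)
  ri <- saaty_random_index(n)
  cr <- if (n <= 2) 0 else ci / ri
  if (cr >= 0.1) {
    warn(paste0("AHP judgment matrix is inconsistent (CR = ",
                format(round(cr, 4)), " >= 0.1)"))
  }
  structure(
    list(
      weights = weight_vector(labels, w, method = "ahp"),
      lambda_max = lambda_max, ci = ci, cr = cr,
      consistent = cr < 0.1
    ),
    class = "ahp_weights"
  )
}

validate_judgment_matrix <- function(J, tol = 1e-9) {
  if (any(!is.finite(J)) || any(J <= 0)) {
    abort("judgment matrix entries must be positive and finite")
  }
  if (any(abs(diag(J) - 1) > tol)) {
    abort("judgment matrix diagonal must be 1")
  }
  if (any(abs(J * t(J) - 1) > 1e-6)) {
    abort("judgment matrix must be reciprocal: J[j, i] = 1 / J[i, j]")
  }
  if (any(J < 1 / 9 - 1e-9 | J > 9 + 1e-9)) {
    abort("judgment matrix entries must lie in [1/9, 9] (Saaty scale)")
  }
  invisible(J)
}

# Saaty's random consistency index for n = 1..15 (standard table; values
# beyond 10 from the usual extension)
saaty_random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.54, 1.56, 1.57, 1.59)
  ri[n]
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat("AHP weights (lambda_max = ", format(round(x$lambda_max, 4)),
      ", CI = ", format(round(x$ci, 4)),
      ", CR = ", format(round(x$cr, 4)),
      if (x$consistent) ", consistent" else ", INCONSISTENT", ")\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' @export
#' @method tidy ahp_weights
tidy.ahp_weights <- function(x, ...) x$weights

#' @export
#' @method glance ahp_weights
glance.ahp_weights <- function(x, ...) {
  tibble(lambda_max = x$lambda_max, ci = x$ci, cr = x$cr,
         consistent = x$consistent)
}

#' Illustrative judgment matrix for grafting suitability
#'
#' The expert judgment matrices behind published grafting-machine weights
#' are typically not released, so the package ships an illustrative 1--9
#' scale matrix over the default 12 indicators. It encodes the field's
#' stated priority: hypocotyl length and stem diameter dominate every
#' other indicator (seedlings whose hypocotyl or stem miss the machine's
#' tolerance cannot be grafted at all), mechanical strengths matter next,
#' and biomass indicators least. It is a documented example, not elicited
#' expert data.
#'
#' @param registry Indicator registry supplying the labels.
#' @return A square reciprocal matrix with dimnames.
#' @export
example_judgment_matrix <- function(registry = indicator_registry()) {
  labels <- registry$indicator
  # priority classes: 1 = decisive, 2 = important, 3 = minor
  cls <- c(
    hypocotyl_length = 1, stem_diameter = 1,
    radial_compression_force = 2, axial_compression_force = 2,
    bending_strength = 2, shear_strength = 2,
    seedling_strength_index = 2,
    fresh_weight = 3, shoot_dry_weight = 3, root_dry_weight = 3,
    plant_height = 3, moisture_content = 3
  )[labels]
  score <- c(`1` = 9, `2` = 3, `3` = 1)[as.character(cls)]
  J <- outer(score, score, `/`)
  diag(J) <- 1
  dimnames(J) <- list(labels, labels)
  J
}

#' Read / write a judgment matrix
#'
#' Round-trips a square judgment matrix through CSV with indicator names
#' as the first column and as the header.
#'
#' @param path Path to a CSV file.
#' @param J A judgment matrix with dimnames.
#' @return `read_judgment_matrix()` returns a validated matrix;
#'   `write_judgment_matrix()` returns `path` invisibly.
#' @export
read_judgment_matrix <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  labels <- d[[1]]
  J <- as.matrix(d[, -1])
  rownames(J) <- labels
  if (!identical(colnames(J), labels)) {
    abort("judgment matrix file must have matching row and column labels")
  }
  validate_judgment_matrix(J)
  J
}

#' @rdname read_judgment_matrix
#' @export
write_judgment_matrix <- function(J, path) {
  d <- bind_cols(tibble(indicator = rownames(J)), as_tibble(J))
  readr::write_csv(d, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
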