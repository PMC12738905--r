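test_that("AHP recovers weights from consistent judgment matrices", {
  # all-ones matrix: perfectly consistent, uniform weights
  J <- matrix(1, 3, 3)
  res <- ahp_weights(J, labels = c("a", "b", "c"))
  expect_equal(res$weights$weight, rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(res$ci, 0, tolerance = 1e-10)
  expect_equal(res$cr, 0, tolerance = 1e-10)
  expect_true(res$consistent)

  # a consistent matrix built from known weights is recovered exactly
  w_true <- c(0.5, 0.3, 0.2)
  J <- outer(w_true, w_true, `/`)
  res <- ahp_weights(J, labels = c("a", "b", "c"))
  expect_equal(res$weights$weight, w_true, tolerance = 1e-9)
  expect_lt(res$cr, 1e-9)

  # cyclic preferences: maximally inconsistent, flagged
  J3 <- matrix(c(1, 9, 1 / 9,
                 1 / 9, 1, 9,
                 9, 1 / 9, 1), 3, 3, byrow = TRUE)
  expect_warning(res3 <- ahp_weights(J3), "inconsistent")
  expect_gte(res3$cr, 0.1)
  expect_false(res3$consistent)
})

test_that("AHP validates the judgment matrix structure", {
  J <- matrix(c(1, 2, 3, 1), 2, 2)  # not reciprocal
  expect_error(ahp_weights(J), "reciprocal")
  J <- matrix(c(1, 12, 1 / 12, 1), 2, 2, byrow = TRUE)  # off Saaty scale
  expect_error(ahp_weights(J), "1/9")
  expect_error(ahp_weights(matrix(1, 1, 1)), "square")
})

test_that("entropy weights follow the dispersion principle", {
  # constant column gets ~0 weight, dispersed column ~1
  X <- tibble::tibble(flat = rep(0.5, 20),
                      spread = c(rep(0.01, 10), rep(0.99, 10)))
  w <- entropy_weights(X, registry = NULL)
  expect_lt(w$weight[w$indicator == "flat"], 0.05)
  expect_gt(w$weight[w$indicator == "spread"], 0.95)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)

  # identical columns share weight equally
  X <- tibble::tibble(a = c(0.2, 0.5, 0.9), b = c(0.2, 0.5, 0.9))
  w <- entropy_weights(X, registry = NULL)
  expect_equal(w$weight, c(0.5, 0.5), tolerance = 1e-12)

  # 3x2 toy matrix against a hand-computed chain
  X <- tibble::tibble(a = c(0.1, 0.4, 0.5), b = c(0.3, 0.3, 0.4))
  p_a <- X$a / sum(X$a); p_b <- X$b / sum(X$b)
  e_a <- -sum(p_a * log(p_a)) / log(3)
  e_b <- -sum(p_b * log(p_b)) / log(3)
  w_hand <- c(1 - e_a, 1 - e_b) / sum(c(1 - e_a, 1 - e_b))
  w <- entropy_weights(X, registry = NULL)
  expect_equal(w$weight, w_hand, tolerance = 1e-12)

  expect_error(entropy_weights(X[1, ], registry = NULL), "at least 2")
  expect_error(
    entropy_weights(tibble::tibble(a = c(0, 0), b = c(0.1, 0.2)),
                    registry = NULL),
    "all-zero"
  )
})

test_that("game combination solves the deviation-minimizing system", {
  a <- weight_vector(c("x", "y"), c(0.6, 0.4), "ahp")
  b <- weight_vector(c("x", "y"), c(0.2, 0.8), "entropy")

  # single input: normalization of one coefficient
  g1 <- game_combination(list(a))
  expect_equal(g1$alpha_norm, 1)
  expect_equal(g1$weights$weight, a$weight)

  # identical inputs: zero deviation, combination equals them (the Gram
  # system is singular and resolved by the pseudo-solution)
  expect_warning(g2 <- game_combination(list(a, a)), "singular")
  expect_equal(g2$weights$weight, a$weight, tolerance = 1e-12)

  # explicit 2x2 solve as an independent oracle
  C <- cbind(a$weight, b$weight)
  G <- crossprod(C)
  alpha <- solve(G, diag(G))
  alpha_n <- alpha / sum(alpha)
  expected <- as.numeric(C %*% alpha_n)
  g3 <- game_combination(list(a, b))
  expect_equal(g3$alpha_norm, alpha_n, tolerance = 1e-12)
  expect_equal(g3$weights$weight, expected, tolerance = 1e-12)

  # gram matrix structure
  expect_equal(g3$gram, G, ignore_attr = TRUE)
  expect_true(isSymmetric(g3$gram))
})

test_that("combination coefficients satisfy the per-input deviation conditions", {
  # the method's first-order conditions: for every input i,
  # c_i . (sum_k alpha_k c_k) = c_i . c_i
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(3:8, 1)
    L <- sample(2:3, 1)
    C <- vapply(seq_len(L), function(k) {
      w <- runif(m); w / sum(w)
    }, numeric(m))
    inputs <- lapply(seq_len(L), function(k) {
      weight_vector(paste0("i", seq_len(m)), C[, k])
    })
    g <- tryCatch(suppressWarnings(game_combination(inputs)),
                  error = function(e) NULL)
    if (is.null(g)) next  # negative combined weights are a documented error
    comb_raw <- as.numeric(C %*% g$alpha_raw)
    for (i in seq_len(L)) {
      expect_equal(sum(C[, i] * comb_raw), sum(C[, i]^2), tolerance = 1e-8)
    }
    # combination is reassembled from the normalized coefficients
    expect_equal(g$weights$weight,
                 pmax(as.numeric(C %*% g$alpha_norm), 0) /
                   sum(pmax(as.numeric(C %*% g$alpha_norm), 0)),
                 tolerance = 1e-9)
  }
})

test_that("linear solve matches a dense grid solution of the Gram system", {
  # independent route: brute-force the coefficient vector minimizing the
  # residual of the Gram equations over a dense grid
  set.seed(5)
  for (rep in 1:5) {
    m <- sample(3:6, 1)
    C <- vapply(1:2, function(k) {
      w <- runif(m); w / sum(w)
    }, numeric(m))
    G <- crossprod(C)
    alpha_solve <- solve(G, diag(G))
    grid <- as.matrix(expand.grid(a1 = seq(-1, 3, by = 0.01),
                                  a2 = seq(-1, 3, by = 0.01)))
    resid <- apply(grid, 1, function(a) sum((G %*% a - diag(G))^2))
    alpha_grid <- grid[which.min(resid), ]
    expect_lt(max(abs(alpha_grid - alpha_solve)), 0.011)
  }
})

test_that("order of inputs does not change the combination", {
  a <- weight_vector(c("x", "y", "z"), c(0.5, 0.3, 0.2), "ahp")
  b <- weight_vector(c("x", "y", "z"), c(0.2, 0.3, 0.5), "entropy")
  g_ab <- game_combination(list(a, b))
  g_ba <- game_combination(list(b, a))
  expect_equal(g_ab$weights$weight, g_ba$weights$weight, tolerance = 1e-12)
})

test_that("combined weighting pipeline composes AHP and entropy", {
  reg <- tiny_registry()
  # judgment matrix built from the entropy ratios: AHP equals entropy,
  # so the game combination must return that common vector
  X <- tibble::tibble(len = c(100, 70, 40, 10), mass = c(1, 4, 6, 9),
                      defect = c(0.4, 1.6, 2.4, 3.6))
  ent <- entropy_weights(X, reg)
  J <- outer(ent$weight, ent$weight, `/`)
  diag(J) <- 1
  dimnames(J) <- list(reg$indicator, reg$indicator)
  expect_warning(cw <- combined_weights(J, X, reg), "singular")
  expect_equal(sum(cw$weight), 1, tolerance = 1e-9)
  expect_equal(cw$weight, ent$weight, tolerance = 1e-8)

  # manual composition on the same inputs
  ahp <- ahp_weights(J)
  manual <- suppressWarnings(game_combination(list(ahp$weights, ent)))
  expect_equal(cw$weight, manual$weights$weight, tolerance = 1e-12)
})

test_that("priority-encoding judgment matrix puts hypocotyl and stem on top", {
  reg <- indicator_registry()
  J <- example_judgment_matrix(reg)
  d <- small_design_dataset()
  # build a 12-indicator table from twin morphology plus neutral fillers
  set.seed(9)
  X <- tibble::tibble(
    hypocotyl_length = pmin(d$hypocotyl_mm, 150),
    stem_diameter = pmin(d$stem_mm, 5),
    moisture_content = runif(nrow(d), 86, 94),
    fresh_weight = runif(nrow(d), 1, 4),
    shoot_dry_weight = runif(nrow(d), 0.1, 0.4),
    root_dry_weight = runif(nrow(d), 0.1, 0.4),
    plant_height = runif(nrow(d), 50, 200),
    seedling_strength_index = runif(nrow(d), 0.2, 0.8),
    radial_compression_force = runif(nrow(d), 10, 40),
    axial_compression_force = runif(nrow(d), 3, 12),
    bending_strength = runif(nrow(d), 1, 4),
    shear_strength = runif(nrow(d), 1, 4)
  )
  cw <- combined_weights(J, X, reg)
  top <- cw$weight[cw$indicator %in% c("hypocotyl_length", "stem_diameter")]
  rest <- cw$weight[!cw$indicator %in% c("hypocotyl_length", "stem_diameter")]
  expect_true(all(min(top) > rest))
})
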