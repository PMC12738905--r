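#' Differential-evolution configuration
#'
#' Frozen defaults for the inverse-design search: `best1bin` mutation
#' (perturb the incumbent best with a random difference vector, binomial
#' crossover), population multiplier of 15 (the population holds 15
#' members per search dimension, initialized by Latin hypercube), scale
#' factor F drawn uniformly in \[0.5, 1) each generation (dither),
#' crossover probability 0.7, at most 1000 generations, relative
#' convergence tolerance 0.01 on the spread of population energies,
#' final local polish enabled, seed 42.
#'
#' @param strategy Mutation strategy; only `"best1bin"` is implemented.
#' @param population Population multiplier: members per dimension.
#' @param f_range Range from which the scale factor is sampled each
#'   generation.
#' @param cr Crossover probability.
#' @param max_iterations Generation limit.
#' @param tolerance Convergence tolerance: stop when
#'   `sd(energies) <= tolerance * |mean(energies)|`.
#' @param polish Run a bounded quasi-Newton refinement from the best
#'   point after the evolution?
#' @param seed Integer seed.
#' @return A list of class `"de_config"`.
#' @export
de_config <- function(strategy = "best1bin", population = 15,
                      f_range = c(0.5, 1), cr = 0.7,
                      max_iterations = 1000, tolerance = 0.01,
                      polish = TRUE, seed = 42) {
  if (!identical(strategy, "best1bin")) {
    abort("only the 'best1bin' strategy is implemented")
  }
  if (population < 5) abort("population must be >= 5")
  structure(
    list(strategy = strategy, population = population, f_range = f_range,
         cr = cr, max_iterations = max_iterations, tolerance = tolerance,
         polish = polish, seed = seed),
    class = "de_config"
  )
}

#' Differential evolution (best1bin) over box bounds
#'
#' Minimizes `fn` over a box. `fn` must accept a matrix with one
#' candidate per row and return a numeric vector of objective values —
#' the population is evaluated in one call per generation, which keeps
#' surrogate-model objectives (e.g. boosted-tree predictions) fast.
#' Every candidate ever evaluated can be archived together with its
#' objective value via `collect_below`, which is how the two-stage
#' recipe designer gathers its stage-one feasible set.
#'
#' @param fn Vectorized objective: `function(X)` with `X` an `n x d`
#'   matrix, returning `n` values.
#' @param lower,upper Numeric bound vectors of length d.
#' @param config A [de_config()].
#' @param collect_below Archive every evaluated candidate with objective
#'   strictly below this value (`Inf` archives everything, `NULL`
#'   nothing).
#' @return List with `par` (best vector), `value`, `iterations`,
#'   `converged`, `trace` (tibble: generation, best value), and
#'   `archive` (tibble of collected candidates with their values).
#' @export
differential_evolution <- function(fn, lower, upper, config = de_config(),
                                   collect_below = NULL) {
  d <- length(lower)
  if (length(upper) != d || any(lower >= upper)) {
    abort("need lower < upper in every dimension")
  }
  np <- config$population * d
  set.seed(config$seed)

  clip <- function(X) {
    X <- pmax(X, matrix(lower, nrow(X), d, byrow = TRUE))
    pmin(X, matrix(upper, nrow(X), d, byrow = TRUE))
  }

  arch_X <- NULL
  arch_v <- NULL
  keep <- function(X, v) {
    if (is.null(collect_below)) return(invisible(NULL))
    sel <- v < collect_below
    if (any(sel)) {
      arch_X <<- rbind(arch_X, X[sel, , drop = FALSE])
      arch_v <<- c(arch_v, v[sel])
    }
    invisible(NULL)
  }

  pop <- lhs::randomLHS(np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  energy <- fn(pop)
  keep(pop, energy)

  trace <- tibble(generation = 0L, best = min(energy))
  converged <- FALSE
  gen <- 0L
  for (gen in seq_len(config$max_iterations)) {
    best_i <- which.min(energy)
    Fscale <- runif(1, config$f_range[1], config$f_range[2])

    r1 <- integer(np); r2 <- integer(np)
    for (i in seq_len(np)) {
      pick <- sample(setdiff(seq_len(np), i), 2)
      r1[i] <- pick[1]; r2[i] <- pick[2]
    }
    mutant <- matrix(pop[best_i, ], np, d, byrow = TRUE) +
      Fscale * (pop[r1, , drop = FALSE] - pop[r2, , drop = FALSE])

    cross <- matrix(runif(np * d) < config$cr, np, d)
    forced <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
    cross[forced] <- TRUE
    trial <- pop
    trial[cross] <- mutant[cross]
    trial <- clip(trial)

    trial_energy <- fn(trial)
    keep(trial, trial_energy)
    improved <- trial_energy < energy
    pop[improved, ] <- trial[improved, , drop = FALSE]
    energy[improved] <- trial_energy[improved]

    trace <- bind_rows(trace, tibble(generation = gen, best = min(energy)))
    if (sd(energy) <= config$tolerance * abs(mean(energy)) + 1e-12) {
      converged <- TRUE
      break
    }
  }

  best_i <- which.min(energy)
  par <- pop[best_i, ]
  value <- energy[best_i]

  if (config$polish) {
    scalar_fn <- function(x) fn(matrix(x, nrow = 1))
    pol <- tryCatch(
      optim(par, scalar_fn, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(pol) && is.finite(pol$value) && pol$value < value) {
      par <- pol$par
      value <- pol$value
      keep(matrix(par, nrow = 1), value)
    }
  }

  archive <- if (is.null(arch_X)) {
    tibble()
  } else {
    out <- as_tibble(as.data.frame(arch_X), .name_repair = "minimal")
    names(out) <- paste0("x", seq_len(d))
    out$value <- arch_v
    out
  }
  list(par = par, value = value, iterations = gen, converged = converged,
       trace = trace, archive = archive)
}
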