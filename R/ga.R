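#' Multi-response fitness: sum of min-max normalized responses
#'
#' Aggregates the four responses into a single maximization objective as
#' the sum of each response scaled by its normalization range, giving a
#' fitness in [0, 4] when responses stay inside their ranges (consistent
#' with the study's reported best fitness of 3.087). Normalization ranges
#' default to the observed response ranges of the training design.
#'
#' @param responses Numeric response vector (or matrix, one row per point).
#' @param lo,hi Normalization range per response.
#' @param direction `+1` to maximize a response (default for all four),
#'   `-1` to minimize it (its scaled term is flipped).
#' @return Numeric fitness value(s).
#' @export
fitness_normalized <- function(responses, lo, hi,
                               direction = rep(1, length(lo))) {
  if (any(hi <= lo)) stop("normalization ranges must be non-degenerate")
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  s <- sweep(sweep(responses, 2, lo), 2, hi - lo, "/")
  if (any(s < -1 | s > 2))
    warning("response outside 3x its normalization range; ",
            "surrogate extrapolation is unreliable")
  s <- sweep(s, 2, direction == -1, function(x, flip) ifelse(flip, 1 - x, x))
  drop(rowSums(s))
}

#' Genetic-algorithm settings
#'
#' @param pop_size Population size (>= 4; default 50).
#' @param generations Number of generations (default 200).
#' @param p_crossover Blend-crossover probability (default 0.8).
#' @param p_mutation Per-gene Gaussian mutation probability (default 0.1).
#' @param mutation_sigma Mutation scale as a fraction of each factor range
#'   (default 0.05).
#' @param elitism Number of elites copied unchanged (default 2).
#' @param tournament Tournament size for selection (default 3).
#' @param blend_alpha Blend-crossover expansion factor (default 0.5).
#' @param seed Seed for all GA randomness.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 50, generations = 200, p_crossover = 0.8,
                       p_mutation = 0.1, mutation_sigma = 0.05, elitism = 2,
                       tournament = 3, blend_alpha = 0.5, seed = 1) {
  if (pop_size < 4) stop("population size must be >= 4")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_sigma = mutation_sigma, elitism = elitism,
                 tournament = tournament, blend_alpha = blend_alpha,
                 seed = seed),
            class = "ga_control")
}

#' Real-coded genetic algorithm over a bounded box
#'
#' Maximizes a scalar fitness over `[lower, upper]` with tournament
#' selection, blend (BLX-alpha) crossover, Gaussian mutation scaled to each
#' factor range, boundary clipping and elitism. Individuals whose fitness
#' evaluates non-finite are assigned the worst fitness and counted. With
#' elitism the per-generation best-fitness trace is non-decreasing. All
#' randomness derives from the control seed, so results are reproducible.
#'
#' @param fn Fitness function: numeric vector (one point) -> scalar, higher
#'   is better.
#' @param lower,upper Box bounds (finite, ordered).
#' @param control A [ga_control()].
#' @param init Optional matrix of points (rows) seeded into the initial
#'   population, e.g. the training-design points.
#' @return An object of class `ga_result`: `best_point`, `best_fitness`,
#'   `solution_set` (deduplicated final population with fitness, sorted
#'   decreasing), `history` (best fitness per generation),
#'   `n_nonfinite` (count of non-finite evaluations).
#' @export
ga_optimize <- function(fn, lower, upper, control = ga_control(),
                        init = NULL) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower))
    stop("bounds must be finite with lower < upper")
  rng <- upper - lower
  clip <- function(P) pmin(pmax(P, matrix(lower, nrow(P), d, byrow = TRUE)),
                           matrix(upper, nrow(P), d, byrow = TRUE))
  n_nonfinite <- 0L
  eval_pop <- function(P) {
    f <- apply(P, 1, function(x) {
      v <- fn(x)
      if (!is.finite(v)) NA_real_ else v
    })
    bad <- is.na(f)
    n_nonfinite <<- n_nonfinite + sum(bad)
    f[bad] <- -Inf
    f
  }

  set.seed(control$seed)
  P <- matrix(stats::runif(control$pop_size * d), ncol = d)
  P <- sweep(sweep(P, 2, rng, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- clip(as.matrix(init))
    n_seed <- min(nrow(init), control$pop_size)
    P[seq_len(n_seed), ] <- init[seq_len(n_seed), , drop = FALSE]
  }
  f <- eval_pop(P)
  history <- numeric(control$generations)

  for (gen in seq_len(control$generations)) {
    ord <- order(f, decreasing = TRUE)
    elite <- P[ord[seq_len(control$elitism)], , drop = FALSE]
    pick <- function() {
      cand <- sample.int(control$pop_size, control$tournament, replace = TRUE)
      cand[which.max(f[cand])]
    }
    children <- matrix(0, control$pop_size - control$elitism, d)
    i <- 1
    while (i <= nrow(children)) {
      p1 <- P[pick(), ]; p2 <- P[pick(), ]
      if (stats::runif(1) < control$p_crossover) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        span <- hi - lo
        c1 <- stats::runif(d, lo - control$blend_alpha * span,
                           hi + control$blend_alpha * span)
        c2 <- stats::runif(d, lo - control$blend_alpha * span,
                           hi + control$blend_alpha * span)
      } else {
        c1 <- p1; c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1 <= nrow(children)) children[i + 1, ] <- c2
      i <- i + 2
    }
    mut <- matrix(stats::runif(length(children)) < control$p_mutation,
                  nrow(children), d)
    noise <- matrix(stats::rnorm(length(children), sd = 1), nrow(children), d)
    noise <- sweep(noise, 2, control$mutation_sigma * rng, "*")
    children <- children + mut * noise
    P <- clip(rbind(elite, children))
    f <- eval_pop(P)
    history[gen] <- max(f)
  }

  best <- which.max(f)
  dedup <- !duplicated(round(P, 6))
  sol <- cbind(P[dedup, , drop = FALSE], fitness = f[dedup])
  sol <- sol[order(sol[, "fitness"], decreasing = TRUE), , drop = FALSE]
  structure(list(best_point = P[best, ], best_fitness = f[best],
                 solution_set = sol, history = history,
                 n_nonfinite = n_nonfinite, control = control),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.4f at (%s); %d distinct solutions\n",
              x$best_fitness, paste(signif(x$best_point, 6), collapse = ", "),
              nrow(x$solution_set)))
  invisible(x)
}

#' Relative deviation between experimental and predicted optima
#'
#' Per-response percentage deviation `100 * |predicted - experimental| /
#' experimental`, the statistic used to validate a model optimum against a
#' confirmation experiment.
#'
#' @param experimental,predicted Positive response vectors.
#' @return Percentage deviation per response.
#' @examples
#' validate_optimum(16.698, 17.860)  # 6.96
#' @export
validate_optimum <- function(experimental, predicted) {
  if (length(experimental) != length(predicted))
    stop("vectors must have equal length")
  if (any(experimental <= 0)) stop("experimental values must be positive")
  100 * abs(predicted - experimental) / experimental
}
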