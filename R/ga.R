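# Real-coded genetic algorithm used for model calibration.
#
# Tournament selection, blend (BLX-alpha) crossover, Gaussian mutation
# with reflection at the box bounds, and two-member elitism. The run is
# fully determined by its seed; the per-generation best-error series is
# returned as the run log.

#' Genetic-algorithm configuration
#'
#' @param population Population size (default 100, `>= 2`).
#' @param max_generations Generation cap per run.
#' @param tol Convergence tolerance on the change in best error
#'   (default `1e-12`, `> 0`): a run stops when the best error has
#'   improved by less than `tol` over the last `stall` generations.
#' @param stall Stall window (generations) over which the improvement is
#'   measured.
#' @param restarts Number of independent GA runs (default 200).
#' @param seed Integer seed; restart `i` runs under `seed + i`.
#' @param crossover_rate,mutation_rate,mutation_sd,mutation_decay,blx_alpha
#'   Operator settings: fraction of offspring produced by crossover,
#'   per-gene mutation probability, initial mutation standard deviation
#'   as a fraction of the box width, the per-generation geometric decay
#'   of that deviation (annealed mutation, so late generations refine
#'   rather than explore), and the BLX expansion factor.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 100, max_generations = 200, tol = 1e-12,
                      stall = 25, restarts = 200, seed = 1,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      mutation_sd = 0.1, mutation_decay = 0.95, blx_alpha = 0.3) {
  if (population < 2) stop("population must be >= 2")
  if (tol <= 0) stop("tol must be positive")
  structure(
    list(population = population, max_generations = max_generations, tol = tol,
         stall = stall, restarts = restarts, seed = seed,
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         mutation_sd = mutation_sd, mutation_decay = mutation_decay,
         blx_alpha = blx_alpha),
    class = "ga_config"
  )
}

# minimize fn over the box [lower, upper]; returns best vector, best
# error, and the per-generation log
ga_minimize <- function(fn, lower, upper, cfg = ga_config(), seed = cfg$seed) {
  d <- length(lower)
  if (length(upper) != d || any(upper < lower)) stop("infeasible bounds")
  width <- upper - lower
  npop <- cfg$population
  with_seed(seed, {
    pop <- matrix(stats::runif(npop * d, lower, upper), nrow = npop, byrow = TRUE)
    fit <- apply(pop, 1, fn)
    log <- numeric(0)
    for (gen in seq_len(cfg$max_generations)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      log <- c(log, fit[1])
      if (gen > cfg$stall &&
          (log[gen - cfg$stall] - log[gen]) < cfg$tol) break
      elite <- pop[1:2, , drop = FALSE]
      # binary tournaments
      pick <- function() {
        ij <- sample.int(npop, 2)
        if (fit[ij[1]] <= fit[ij[2]]) pop[ij[1], ] else pop[ij[2], ]
      }
      children <- matrix(NA_real_, npop, d)
      for (k in seq_len(npop)) {
        p1 <- pick()
        if (stats::runif(1) < cfg$crossover_rate) {
          p2 <- pick()
          lo <- pmin(p1, p2); hi <- pmax(p1, p2)
          span <- hi - lo
          child <- stats::runif(d, lo - cfg$blx_alpha * span, hi + cfg$blx_alpha * span)
        } else {
          child <- p1
        }
        mut <- stats::runif(d) < cfg$mutation_rate
        if (any(mut)) {
          sd_gen <- cfg$mutation_sd * cfg$mutation_decay^gen
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sd_gen * width[mut])
        }
        # reflect into the box, then clamp (degenerate zero-width genes)
        child <- pmin(pmax(child, 2 * lower - child), 2 * upper - child)
        children[k, ] <- pmin(pmax(child, lower), upper)
      }
      children[1:2, ] <- elite
      pop <- children
      fit <- apply(pop, 1, fn)
    }
    best <- which.min(fit)
    list(par = pop[best, ], error = fit[best], log = log,
         generations = length(log), seed = seed)
  })
}
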