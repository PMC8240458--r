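#' Genetic-algorithm configuration
#'
#' Parameters of the binary genetic search over DMD patterns with PBR as the
#' fitness. Defaults follow the standard binary wavefront-shaping GA: a
#' population of 20 chromosomes initialised at ~50% mirrors ON, uniform
#' crossover at rate 0.6, and mutation either at a constant rate 0.02 or on
#' the decaying schedule \eqn{0.1\,e^{-G/600} + 0.02} (G = generation index),
#' which explores aggressively early and anneals to the constant rate. Each
#' generation, `offspring_per_generation` children are bred from
#' rank-weighted parents, evaluated, merged with the current population, and
#' the best `population_size` individuals survive (so elitism is implicit;
#' `elite_count` individuals are additionally never re-evaluated under noisy
#' fitness).
#'
#' @param generations Number of generations to evolve.
#' @param population_size Number of chromosomes kept (default 20).
#' @param cross_rate Per-gene probability of inheriting from the first
#'   parent, in (0, 1) (default 0.6).
#' @param mutation_mode `"constant"` (default) or `"schedule"`.
#' @param mutation_rate Constant-mode flip probability (default 0.02).
#' @param offspring_per_generation Children bred per generation (default half
#'   the population).
#' @param elite_count Individuals exempt from noisy re-evaluation
#'   (default 1).
#' @param on_fraction ON probability of the initial random chromosomes
#'   (default 0.5).
#' @param reevaluate Re-evaluate the surviving population each generation;
#'   needed when the fitness is stochastic (measurement noise), where it
#'   costs strict monotonicity of the recorded best fitness. Default FALSE.
#' @param seed Integer seed driving the whole evolution.
#' @return A `ga_config` list.
#' @examples
#' cfg <- ga_config(generations = 100, seed = 1)
#' @export
ga_config <- function(generations, population_size = 20, cross_rate = 0.6,
                      mutation_mode = c("constant", "schedule"),
                      mutation_rate = 0.02,
                      offspring_per_generation = max(2L, population_size %/% 2L),
                      elite_count = 1, on_fraction = 0.5,
                      reevaluate = FALSE, seed = 1) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(generations >= 0, population_size >= 2)
  if (cross_rate <= 0 || cross_rate >= 1) stop("`cross_rate` must be in (0, 1)")
  if (mutation_rate <= 0 || mutation_rate > 0.5) {
    stop("`mutation_rate` must be in (0, 0.5]")
  }
  stopifnot(offspring_per_generation >= 1, elite_count >= 0)
  structure(
    list(generations = as.integer(generations),
         population_size = as.integer(population_size),
         cross_rate = cross_rate, mutation_mode = mutation_mode,
         mutation_rate = mutation_rate,
         offspring_per_generation = as.integer(offspring_per_generation),
         elite_count = as.integer(elite_count), on_fraction = on_fraction,
         reevaluate = reevaluate, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Initial random population of binary chromosomes
#'
#' @param n_inputs Chromosome length N (number of mirrors).
#' @param population_size Number of chromosomes.
#' @param on_fraction Per-gene ON probability (default 0.5).
#' @param seed Integer seed.
#' @return Integer 0/1 matrix, one chromosome per column (N x P).
#' @examples
#' pop <- ga_init_population(64, 20, seed = 1)
#' @export
ga_init_population <- function(n_inputs, population_size, on_fraction = 0.5,
                               seed) {
  stopifnot(population_size >= 1)
  if (missing(seed)) stop("`seed` is required for reproducibility")
  pop <- with_stream_seed(
    derive_seed(seed, "ga-init"),
    matrix(stats::rbinom(n_inputs * population_size, 1L, on_fraction),
           nrow = n_inputs, ncol = population_size)
  )
  storage.mode(pop) <- "integer"
  pop
}

#' PBR fitness of a pattern
#'
#' @param pattern Binary vector, or matrix with one pattern per column.
#' @param measure Full-frame measurement callback (e.g. [tm_measure()]).
#' @param target_index Focus pixel index.
#' @return PBR value(s), one per pattern.
#' @export
ga_fitness <- function(pattern, measure, target_index) {
  single <- is.null(dim(pattern))
  pats <- if (single) matrix(pattern, ncol = 1) else pattern
  intensity <- measure(t(pats))
  if (is.null(dim(intensity))) intensity <- matrix(intensity, ncol = 1)
  out <- apply(intensity, 2, pbr, target_index = target_index)
  if (single) out[[1]] else out
}

#' Rank-weighted parent selection
#'
#' Samples two distinct parents from a population ranked by fitness
#' (index 1 = best) with probability proportional to a linear rank weight:
#' the best individual has weight `n`, the worst weight 1.
#'
#' @param n Population size (ranked 1..n, best first).
#' @return Integer vector of two distinct indices into the ranked
#'   population.
#' @examples
#' set.seed(1)
#' ga_select_parents(20)
#' @export
ga_select_parents <- function(n) {
  stopifnot(n >= 2)
  sample.int(n, 2, replace = FALSE, prob = n:1)
}

#' Uniform crossover of two parent chromosomes
#'
#' Each gene is inherited from `parent_a` with probability `cross_rate` and
#' from `parent_b` otherwise.
#'
#' @param parent_a,parent_b Binary vectors of equal length.
#' @param cross_rate Probability of inheriting from `parent_a`.
#' @return Binary offspring vector.
#' @export
ga_crossover <- function(parent_a, parent_b, cross_rate = 0.6) {
  stopifnot(length(parent_a) == length(parent_b))
  from_a <- stats::runif(length(parent_a)) < cross_rate
  out <- parent_b
  out[from_a] <- parent_a[from_a]
  out
}

#' Random bit-flip mutation
#'
#' Flips each gene independently with probability `rate`.
#'
#' @param pattern Binary vector.
#' @param rate Flip probability in `[0, 1]`.
#' @return Mutated binary vector.
#' @export
ga_mutate <- function(pattern, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(pattern)
  flip <- stats::runif(length(pattern)) < rate
  pattern[flip] <- 1L - pattern[flip]
  pattern
}

#' Mutation rate at a given generation
#'
#' @param generation_index Generation index G (0-based, >= 0).
#' @param mode `"constant"` or `"schedule"`.
#' @param constant_rate Rate returned in constant mode (default 0.02).
#' @return The mutation rate: `constant_rate`, or
#'   \eqn{0.1\,e^{-G/600} + 0.02} in schedule mode.
#' @examples
#' ga_mutation_rate(0, "schedule") # 0.12
#' @export
ga_mutation_rate <- function(generation_index, mode = c("constant", "schedule"),
                             constant_rate = 0.02) {
  stopifnot(generation_index >= 0)
  mode <- match.arg(mode)
  if (mode == "constant") constant_rate
  else 0.1 * exp(-generation_index / 600) + 0.02
}

#' Evolve a focusing mask by genetic search
#'
#' Runs the generational loop: breed offspring from rank-weighted parents by
#' uniform crossover and mutation, evaluate their PBR through the medium,
#' merge with the current population and keep the best. The run is
#' deterministic given `config$seed` when the measurement callback is
#' noiseless.
#'
#' @param config A [ga_config()].
#' @param measure Full-frame measurement callback.
#' @param target_index Focus pixel index.
#' @param n_inputs Chromosome length N.
#' @return An object of class `ga_run`: list with `best_pattern`,
#'   `best_pbr`, `history` (data frame: `generation`, `best_pbr`,
#'   `mean_pbr`, `mutation_rate`), and `config`.
#' @examples
#' tm <- sample_tm(32, 64, seed = 1)
#' run <- ga_evolve(ga_config(generations = 20, seed = 2),
#'                  tm_measure(tm), central_target(tm), 32)
#' @export
ga_evolve <- function(config, measure, target_index, n_inputs) {
  stopifnot(inherits(config, "ga_config"))
  pop <- ga_init_population(n_inputs, config$population_size,
                            config$on_fraction, config$seed)
  fit <- ga_fitness(pop, measure, target_index)
  ord <- order(-fit)
  pop <- pop[, ord, drop = FALSE]
  fit <- fit[ord]
  gens <- config$generations
  history <- data.frame(
    generation = seq_len(gens + 1L) - 1L,
    best_pbr = NA_real_, mean_pbr = NA_real_, mutation_rate = NA_real_
  )
  history[1, 2:4] <- c(fit[1], mean(fit),
                       ga_mutation_rate(0, config$mutation_mode,
                                        config$mutation_rate))
  withr::local_seed(derive_seed(config$seed, "ga-evolve"))
  noff <- config$offspring_per_generation
  for (g in seq_len(gens)) {
    rate <- ga_mutation_rate(g, config$mutation_mode, config$mutation_rate)
    offspring <- vapply(seq_len(noff), function(j) {
      pr <- ga_select_parents(config$population_size)
      ga_mutate(
        ga_crossover(pop[, pr[1]], pop[, pr[2]], config$cross_rate),
        rate
      )
    }, integer(n_inputs))
    off_fit <- ga_fitness(offspring, measure, target_index)
    if (config$reevaluate && config$elite_count < config$population_size) {
      keep <- seq_len(config$elite_count)
      rest <- setdiff(seq_len(config$population_size), keep)
      if (length(rest)) {
        fit[rest] <- ga_fitness(pop[, rest, drop = FALSE], measure,
                                target_index)
      }
    }
    all_pop <- cbind(pop, offspring)
    all_fit <- c(fit, off_fit)
    ord <- order(-all_fit)[seq_len(config$population_size)]
    pop <- all_pop[, ord, drop = FALSE]
    fit <- all_fit[ord]
    history[g + 1L, 2:4] <- c(fit[1], mean(fit), rate)
  }
  structure(
    list(best_pattern = pop[, 1], best_pbr = fit[1], history = history,
         config = config),
    class = "ga_run"
  )
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "<ga_run> %d generations, best PBR %.2f (population %d, seed %d)\n",
    x$config$generations, x$best_pbr, x$config$population_size,
    x$config$seed
  ))
  invisible(x)
}
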