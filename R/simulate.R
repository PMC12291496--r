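#' Multiplicative fitness of individuals
#'
#' Relative fitness is the product over insertion loci of `1 + h*s` for
#' heterozygous loci and `1 + s` for homozygous loci (a locus present on both
#' haplotypes counts once). Cluster insertions have `s = 0` and contribute a
#' factor of 1. The product is clamped below at `fitness_floor` (with a
#' warning from the stepping functions when triggered) so that
#' fitness-proportional sampling never degenerates.
#'
#' @param pop A `population` or a single individual.
#' @param h Dominance coefficient.
#' @param layout A [genome_layout()] (only used for individuals supplied
#'   outside a population; any layout works since fitness ignores position).
#' @param fitness_floor Lower clamp.
#' @return Numeric vector of fitness values (> 0).
#' @export
#' @examples
#' ind <- make_individual(pos1 = 100, s1 = -0.1, pos2 = 100, s2 = -0.1)
#' population_fitness(list(ind))  # 1 + s = 0.9
population_fitness <- function(pop, h = 0.5, layout = genome_layout(0),
                               fitness_floor = 1e-9) {
  if (!is.null(pop$h1)) pop <- list(pop)  # single individual
  cpp_fitness(unclass(pop), h, fitness_floor, unclass(layout))
}

#' Trap-model transposition step for one individual
#'
#' If the individual carries any piRNA-cluster insertion it is silenced and
#' returned unchanged. Otherwise each element copy (each locus counted once
#' per haplotype it occupies) transposes with probability `u`, placing one
#' new insertion at a uniformly random unoccupied genome position on a
#' uniformly random haplotype; the new insertion gets `s = 0` inside a
#' cluster, else `s = -|Beta(alpha, beta)|`. With probability `v` a
#' transposing copy is excised from its source site. All decisions are made
#' against the pre-transposition state.
#'
#' @param ind An individual (see [make_individual()]).
#' @param params A [model_params()].
#' @param layout A [genome_layout()].
#' @return The individual after transposition.
#' @export
transpose_individual <- function(ind, params, layout = genome_layout(params$f_regulatory)) {
  cpp_transpose_individual(ind, params$u, params$v, params$alpha,
                           params$beta, unclass(layout))
}

#' One recombinant gamete from an individual
#'
#' Crossover breakpoints per chromosome follow a Poisson process with rate
#' `recomb_rate` per bp; chromosomes assort independently; the gamete copies
#' insertions from alternating parental haplotypes between breakpoints.
#'
#' @param ind An individual.
#' @param layout A [genome_layout()].
#' @return Haplotype matrix with columns `pos`, `s`.
#' @export
make_gamete <- function(ind, layout) {
  cpp_make_gamete(ind, unclass(layout))
}

#' Advance a population by one generation
#'
#' Produces `census_n` offspring. Each offspring draws two distinct parents
#' with probability proportional to fitness (obligatory outcrossing), each
#' parent contributes one recombinant gamete, and transposition acts on the
#' zygote (decisions against its inherited, pre-transposition genome).
#'
#' @param pop A `population`.
#' @param params A [model_params()].
#' @param wave A [wave_config()] (supplies the census size).
#' @param layout A [genome_layout()]; defaults to the population's own.
#' @param fitness_floor Lower clamp for fitness.
#' @return The next-generation `population`.
#' @export
step_generation <- function(pop, params, wave,
                            layout = attr(pop, "layout"),
                            fitness_floor = 1e-9) {
  out <- cpp_step_generation(unclass(pop), wave$census_n, params$u, params$v,
                             params$alpha, params$beta, params$h,
                             fitness_floor, unclass(layout))
  structure(out, class = "population", layout = layout)
}

#' Run one invasion replicate
#'
#' Initializes founders and advances the population generation by
#' generation, recording the population mean copies per haploid genome at
#' the requested generations.
#'
#' @param params A [model_params()].
#' @param wave A [wave_config()].
#' @param layout A [genome_layout()].
#' @param generations Number of generations to simulate; defaults to the
#'   last recorded generation.
#' @param record Generations at which to record the mean copy number.
#' @param lambda Founder Poisson rate; defaults to [solve_lambda()] against
#'   the wave's empirical starting copy number.
#' @param fitness_floor Lower clamp for fitness.
#' @param return_population Also return the final population.
#' @return A tibble with columns `generation`, `copy_number`; if
#'   `return_population` the final `population` is attached as attribute
#'   `"population"`.
#' @export
#' @examples
#' set.seed(1)
#' p <- model_params(0.189, 0.014, 0.277, 0.484, 10.327)
#' run_invasion(p, wave_config(1), generations = 10, record = c(0, 10))
run_invasion <- function(params, wave,
                         layout = genome_layout(params$f_regulatory),
                         generations = max(record),
                         record = wave$recorded_generations,
                         lambda = NULL, fitness_floor = 1e-9,
                         return_population = FALSE) {
  stopifnot(generations >= max(record))
  if (is.null(lambda))
    lambda <- solve_lambda(wave$initial_target_cn, params$p_carrier,
                           wave$zygosity)
  res <- cpp_run_invasion(wave$n_lines, wave$flies_per_line,
                          params$p_carrier, lambda,
                          wave$zygosity == "homozygous",
                          params$u, params$v, params$alpha, params$beta,
                          params$h, fitness_floor, unclass(layout),
                          wave$census_n, as.integer(record),
                          as.integer(generations), return_population)
  out <- tibble::tibble(generation = res$generation,
                        copy_number = res$copy_number)
  if (return_population)
    attr(out, "population") <- structure(res$population,
                                         class = "population",
                                         layout = layout)
  out
}

#' Replicate-averaged invasion trajectory
#'
#' Runs `n_reps` independent replicates and returns the element-wise mean
#' copy number at each recorded generation. Per-replicate seeds are derived
#' deterministically from `seed`, so the result is reproducible and
#' individual replicates are independent.
#'
#' @inheritParams run_invasion
#' @param n_reps Number of replicates to average.
#' @param seed Master seed; each replicate folds its index into this seed.
#' @param keep_replicates Also return the per-replicate trajectories.
#' @return A tibble `generation`, `copy_number` (the replicate mean); with
#'   `keep_replicates`, attribute `"replicates"` holds a matrix
#'   (replicates x generations).
#' @export
replicate_mean <- function(params, wave,
                           layout = genome_layout(params$f_regulatory),
                           n_reps = 100, seed = NULL,
                           generations = max(record),
                           record = wave$recorded_generations,
                           keep_replicates = FALSE) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  runs <- matrix(NA_real_, nrow = n_reps, ncol = length(record))
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    tr <- run_invasion(params, wave, layout, generations, record)
    runs[i, ] <- tr$copy_number
  }
  colnames(runs) <- record
  out <- tibble::tibble(generation = as.integer(record),
                        copy_number = unname(colMeans(runs)))
  if (keep_replicates) attr(out, "replicates") <- runs
  out
}
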