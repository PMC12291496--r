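#' Poisson rate for founder insertion counts
#'
#' Solves for the rate lambda of the Poisson number of insertion loci per
#' carrier line such that the expected population mean copy number per
#' haploid genome at generation 0 equals the empirical target. Heterozygous
#' loci contribute 1/2 copy per haploid genome, homozygous loci contribute 1,
#' so lambda = target / (p_carrier * 0.5) for heterozygous founders and
#' target / p_carrier for homozygous founders.
#'
#' @param target_cn Target mean copies per haploid genome (>= 0).
#' @param p_carrier Probability that a line carries the element.
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @return Poisson rate lambda (insertion loci per carrier line).
#' @export
#' @examples
#' solve_lambda(0.86, 0.189, "heterozygous")
solve_lambda <- function(target_cn, p_carrier,
                         zygosity = c("heterozygous", "homozygous")) {
  zygosity <- match.arg(zygosity)
  stopifnot(target_cn >= 0, p_carrier >= 0, p_carrier <= 1)
  if (target_cn == 0) return(0)
  if (p_carrier == 0)
    stop("p_carrier = 0 cannot reach a positive target copy number")
  per_locus <- if (zygosity == "heterozygous") 0.5 else 1
  target_cn / (p_carrier * per_locus)
}

#' Initialize a founder population
#'
#' Builds the generation-0 population by mixing `n_lines` isogenic founder
#' lines of `flies_per_line` flies each. Each line carries the element with
#' probability `p_carrier`; carrier lines receive Poisson(lambda) distinct
#' insertion loci at uniformly random genome positions, heterozygous (wave 1)
#' or homozygous (wave 2). Selection coefficients are drawn from the Beta DFE
#' (0 inside piRNA clusters). Lines with a cluster insertion are silenced
#' from generation 0.
#'
#' Randomness is driven by R's RNG: call `set.seed()` for reproducibility.
#'
#' @param params A [model_params()].
#' @param wave A [wave_config()].
#' @param layout A [genome_layout()]; defaults to the standard layout with
#'   the parameters' `f_regulatory`.
#' @param lambda Poisson rate; defaults to [solve_lambda()] against the
#'   wave's empirical starting copy number.
#' @param fitness_floor Lower clamp for individual fitness.
#' @return A `population` object (list of individuals, each with haplotype
#'   matrices `h1`, `h2` of columns `pos`, `s`).
#' @export
init_founders <- function(params, wave, layout = genome_layout(params$f_regulatory),
                          lambda = NULL, fitness_floor = 1e-9) {
  stopifnot(inherits(params, "model_params"), inherits(wave, "wave_config"),
            inherits(layout, "genome_layout"))
  if (is.null(lambda))
    lambda <- solve_lambda(wave$initial_target_cn, params$p_carrier,
                           wave$zygosity)
  pop <- cpp_init_founders(wave$n_lines, wave$flies_per_line,
                           params$p_carrier, lambda,
                           wave$zygosity == "homozygous",
                           params$alpha, params$beta,
                           unclass(layout), params$h, fitness_floor)
  structure(pop, class = "population", layout = layout)
}

#' Mean copies per haploid genome of a population
#'
#' Total insertion copies across both haplotypes of all individuals divided
#' by twice the census.
#'
#' @param pop A `population`.
#' @return Mean haploid copy number.
#' @export
mean_copy_number <- function(pop) cpp_mean_cn(unclass(pop))

#' Which individuals are silenced by the trap model?
#'
#' An individual is silenced iff any insertion on either haplotype lies in a
#' piRNA cluster; silenced individuals have zero transposition activity.
#'
#' @param pop A `population`.
#' @param layout A [genome_layout()]; defaults to the population's own.
#' @return Logical vector over individuals.
#' @export
is_silenced <- function(pop, layout = attr(pop, "layout")) {
  cpp_silenced(unclass(pop), unclass(layout))
}

#' Construct a single individual from insertion positions
#'
#' Convenience constructor for tests and examples.
#'
#' @param pos1,s1 Positions and selection coefficients on haplotype 1.
#' @param pos2,s2 Positions and selection coefficients on haplotype 2.
#' @return Individual (list of matrices `h1`, `h2`).
#' @export
make_individual <- function(pos1 = numeric(), s1 = numeric(),
                            pos2 = numeric(), s2 = numeric()) {
  stopifnot(length(pos1) == length(s1), length(pos2) == length(s2))
  hap <- function(p, s) {
    m <- cbind(pos = as.numeric(p), s = as.numeric(s))
    m[order(m[, 1]), , drop = FALSE]
  }
  list(h1 = hap(pos1, s1), h2 = hap(pos2, s2))
}

#' Haploid copy number of one individual
#' @param ind An individual.
#' @return Copies per haploid genome (total copies / 2).
#' @export
individual_cn <- function(ind) (nrow(ind$h1) + nrow(ind$h2)) / 2
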