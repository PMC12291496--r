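#' Default exploration bounds for the invasion model parameters
#'
#' Returns the per-parameter (lo, hi) bounds used for Latin hypercube
#' exploration. The basic model varies five parameters; the extended model
#' additionally varies the dominance coefficient `h` and the excision
#' probability `v`.
#'
#' @param model `"basic"` (5 parameters) or `"extended"` (7 parameters).
#' @return Named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
#' @examples
#' param_bounds()
param_bounds <- function(model = c("basic", "extended")) {
  model <- match.arg(model)
  b <- list(
    p_carrier    = c(0.15, 0.5),
    f_regulatory = c(0.01, 0.1),
    u            = c(0.15, 0.5),
    alpha        = c(0.001, 0.5),
    beta         = c(10, 20)
  )
  if (model == "extended") {
    b$h <- c(0, 1)
    b$v <- c(0, 0.5)
  }
  b
}

#' Model parameters for the invasion simulator
#'
#' One point in the 5- or 7-dimensional parameter space. `h = 0.5` and
#' `v = 0` give the basic (co-dominant, copy-and-paste) model. Setting
#' `alpha = 0` encodes a fully neutral DFE (all selection coefficients 0),
#' which is useful for analytic checks.
#'
#' @param p_carrier Probability that a founder line carries the element.
#' @param f_regulatory Fraction of each chromosome covered by the piRNA
#'   cluster at its end.
#' @param u Per-copy, per-generation transposition probability.
#' @param alpha,beta Shape parameters of the Beta DFE for |s|.
#' @param h Dominance coefficient (heterozygote fitness `1 + h*s`).
#' @param v Excision probability per transposing copy.
#' @param bounds Named list of `c(lo, hi)` bounds to validate against, or
#'   `NULL` to skip bound checking (used for analytic corner cases such as
#'   `f_regulatory = 0`).
#' @return A `model_params` list.
#' @export
#' @examples
#' model_params(0.189, 0.014, 0.277, 0.484, 10.327)
model_params <- function(p_carrier, f_regulatory, u, alpha, beta,
                         h = 0.5, v = 0, bounds = param_bounds("basic")) {
  p <- list(p_carrier = p_carrier, f_regulatory = f_regulatory, u = u,
            alpha = alpha, beta = beta, h = h, v = v)
  stopifnot(vapply(p, is.numeric, logical(1)),
            vapply(p, length, integer(1)) == 1L)
  if (h < 0 || h > 1) stop("h must be in [0, 1]")
  if (v < 0 || v > 1) stop("v must be in [0, 1]")
  if (u < 0 || u > 1) stop("u must be in [0, 1]")
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
      if (p[[nm]] < lo || p[[nm]] > hi)
        stop(sprintf("%s = %g outside bounds [%g, %g]", nm, p[[nm]], lo, hi))
    }
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Invasion model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Genome layout for the simulated fly genome
#'
#' Five chromosomes of 32.4 Mb each (162 Mb total) with a uniform
#' recombination rate, and one piRNA cluster per chromosome occupying the
#' high-coordinate end, of length `f_regulatory * chrom_length`.
#'
#' @param f_regulatory Fraction of each chromosome with regulatory
#'   (piRNA-cluster) properties.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in base pairs.
#' @param recomb_rate Recombination rate per bp per generation.
#' @return A `genome_layout` list; `cluster_len` is in base pairs.
#' @export
genome_layout <- function(f_regulatory, n_chromosomes = 5L,
                          chrom_length = 32.4e6, recomb_rate = 4e-8) {
  stopifnot(f_regulatory >= 0, f_regulatory <= 1,
            n_chromosomes >= 1, chrom_length > 0, recomb_rate >= 0)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    recomb_rate = recomb_rate,
    f_regulatory = f_regulatory,
    cluster_len = f_regulatory * chrom_length
  ), class = "genome_layout")
}

#' piRNA cluster intervals of a genome layout
#'
#' @param layout A [genome_layout()].
#' @return Data frame with 0-based half-open intervals (`start`, `end`) on
#'   the concatenated genome coordinate axis, one row per chromosome.
#' @export
cluster_spans <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  L <- layout$chrom_length
  ends <- seq_len(layout$n_chromosomes) * L
  data.frame(chromosome = seq_len(layout$n_chromosomes) - 1L,
             start = ends - layout$cluster_len, end = ends)
}

#' Is a genome position inside a piRNA cluster?
#'
#' @param pos Positions on the concatenated coordinate axis (base pairs).
#' @param layout A [genome_layout()].
#' @return Logical vector.
#' @export
in_cluster <- function(pos, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  off <- pos %% layout$chrom_length
  off >= layout$chrom_length - layout$cluster_len
}

#' Experimental-wave configuration
#'
#' Describes one of the two experimental-evolution setups: number of founder
#' lines, zygosity of founder insertions, empirical starting copy number, and
#' the sequenced generations. Founder insertions are heterozygous for wave 1
#' (recent invasion) and homozygous for wave 2 (long-inbred founder lines).
#'
#' @param wave 1 or 2.
#' @param census_n Census size kept constant across generations.
#' @param n_lines Number of founder isofemale lines.
#' @param flies_per_line Flies contributed per line.
#' @return A `wave_config` list; `evolved_generations` (the recorded
#'   generations minus generation 0) are the six surrogate tasks.
#' @export
#' @examples
#' wave_config(1)$recorded_generations
wave_config <- function(wave, census_n = 1000L, n_lines = 200L,
                        flies_per_line = 5L) {
  stopifnot(wave %in% c(1, 2))
  recorded <- if (wave == 1) c(0L, 10L, 20L, 30L, 40L, 50L, 60L)
              else c(0L, 10L, 15L, 20L, 25L, 30L, 60L)
  structure(list(
    wave_id = as.integer(wave),
    zygosity = if (wave == 1) "heterozygous" else "homozygous",
    initial_target_cn = if (wave == 1) 0.86 else 6.92,
    census_n = as.integer(census_n),
    n_lines = as.integer(n_lines),
    flies_per_line = as.integer(flies_per_line),
    recorded_generations = recorded,
    evolved_generations = recorded[recorded != 0L]
  ), class = "wave_config")
}
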