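#' Generate pseudo-empirical copy-number time series
#'
#' Produces replicated observed-style tables with the statistical structure
#' the calibration assumes: for each wave, each replicate is one independent
#' simulator run at the true parameters, sampled at the wave's recorded
#' generations, with multiplicative Gaussian observation noise (truncated at
#' 0) standing in for pooled-sequencing copy-number estimation error.
#'
#' @param truth A [model_params()] — the true data-generating parameters.
#' @param seed Master seed; all replicate seeds derive from it.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.05); `cv = 0` gives noise-free trajectories.
#' @param n_replicates Replicates per wave (default 3, as in the
#'   experiments).
#' @param waves Which waves to generate.
#' @return A tibble `wave`, `replicate`, `generation`, `copy_number`,
#'   schema-identical to [read_trajectories()] output.
#' @export
#' @examples
#' truth <- model_params(0.189, 0.014, 0.277, 0.484, 10.327)
#' head(generate_pseudo_empirical(truth, seed = 1))
generate_pseudo_empirical <- function(truth, seed, cv = 0.05,
                                      n_replicates = 3, waves = c(1, 2)) {
  stopifnot(inherits(truth, "model_params"), cv >= 0, n_replicates >= 1)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 2 * length(waves) * n_replicates),
                      ncol = 2)
  rows <- list(); i <- 0
  for (w in waves) {
    wv <- wave_config(w)
    for (r in seq_len(n_replicates)) {
      i <- i + 1
      set.seed(rep_seeds[i, 1])
      tr <- run_invasion(truth, wv)
      set.seed(rep_seeds[i, 2])
      noise <- 1 + rnorm(nrow(tr), 0, cv)
      rows[[i]] <- tibble::tibble(wave = as.integer(w),
                                  replicate = as.integer(r),
                                  generation = tr$generation,
                                  copy_number = pmax(0, tr$copy_number * noise))
    }
  }
  do.call(rbind, rows)
}

#' Load a packaged anchor value
#'
#' Returns one of the packaged empirical anchor values (starting copy
#' numbers, plateau level, top-ranked parameter combination, effective
#' population size, headline DFE summaries) together with a short note on
#' what it is.
#'
#' @param name Fixture name; call with no arguments to list the available
#'   names.
#' @return A list with elements `value` and `source`; with no `name`, the
#'   character vector of fixture names.
#' @export
#' @examples
#' load_fixture("wave1_initial_cn")$value  # 0.86
#' load_fixture()
load_fixture <- function(name = NULL) {
  path <- system.file("extdata", "anchor_values.json", package = "teinvade",
                      mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(name)) return(names(fx))
  if (!name %in% names(fx))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fx), collapse = ", ")))
  fx[[name]]
}
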