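#' Observed copy-number replicates for one wave
#'
#' Wraps a long table (`replicate`, `generation`, `copy_number`, optional
#' `wave`) into the per-wave structure the NRMSE computation uses: a
#' generations-by-replicates matrix over the wave's six evolved generations.
#' Generation 0 rows are retained in `$table` but excluded from the NRMSE
#' matrix, since the surrogate tasks do not cover generation 0.
#'
#' @param df Long data frame of observations.
#' @param wave A [wave_config()] or wave id.
#' @return An `observed_wave` object with elements `wave_id`, `generations`,
#'   `obs` (matrix), `mean` (per-generation replicate mean), `table`.
#' @export
observed_wave <- function(df, wave) {
  wv <- if (inherits(wave, "wave_config")) wave else wave_config(wave)
  if ("wave" %in% names(df)) df <- df[df$wave == wv$wave_id, , drop = FALSE]
  stopifnot(all(c("replicate", "generation", "copy_number") %in% names(df)),
            nrow(df) > 0)
  gens <- wv$evolved_generations
  reps <- sort(unique(df$replicate))
  obs <- matrix(NA_real_, length(gens), length(reps),
                dimnames = list(gens, reps))
  for (j in seq_along(reps)) {
    sub <- df[df$replicate == reps[j], ]
    idx <- match(gens, sub$generation)
    if (anyNA(idx))
      stop(sprintf("replicate %s is missing generations: %s", reps[j],
                   paste(gens[is.na(idx)], collapse = ", ")))
    obs[, j] <- sub$copy_number[idx]
  }
  structure(list(wave_id = wv$wave_id, generations = gens, obs = obs,
                 mean = rowMeans(obs), table = df),
            class = "observed_wave")
}

#' NRMSE between a predicted trajectory and observed replicates
#'
#' For each evolved generation g, the RMSE between the single predicted
#' value and the replicate observations is divided by the replicate-mean
#' observed copy number at g; the normalized values are summed over the six
#' generations.
#'
#' @param predicted Numeric vector of predicted copy numbers, aligned with
#'   `observed$generations` (names, if present, are checked).
#' @param observed An [observed_wave()].
#' @return The summed normalized RMSE (dimensionless).
#' @export
#' @examples
#' ow <- observed_wave(data.frame(replicate = rep(1:3, each = 6),
#'                                generation = rep(c(10, 20, 30, 40, 50, 60), 3),
#'                                copy_number = rep(c(5, 10, 14, 15, 15, 15), 3)),
#'                     wave = 1)
#' nrmse_wave(c(5, 10, 14, 15, 15, 15), ow)  # 0: predictions match exactly
nrmse_wave <- function(predicted, observed) {
  stopifnot(inherits(observed, "observed_wave"),
            length(predicted) == length(observed$generations))
  if (!is.null(names(predicted)) &&
      !identical(as.integer(names(predicted)),
                 as.integer(observed$generations)))
    stop("predicted generations do not match observed generations")
  if (any(observed$mean == 0))
    stop("zero mean observed copy number at some generation")
  rmse_g <- sqrt(rowMeans((observed$obs - predicted)^2))
  sum(rmse_g / observed$mean)
}

#' Rank parameter combinations by summed NRMSE across both waves
#'
#' Computes per-wave NRMSE for every parameter combination, sums them, and
#' ranks ascending (rank 1 = best fit). Ties keep the stable input order.
#'
#' @param params Data frame of parameter combinations (one row each).
#' @param pred_w1,pred_w2 Prediction matrices (rows matching `params`,
#'   columns the waves' evolved generations), e.g. from [gp_predict()].
#' @param obs_w1,obs_w2 [observed_wave()] objects.
#' @return A tibble of fit results sorted by rank: the parameter columns
#'   plus `nrmse_wave1`, `nrmse_wave2`, `nrmse_sum`, `rank`.
#' @export
rank_parameters <- function(params, pred_w1, pred_w2, obs_w1, obs_w2) {
  params <- tibble::as_tibble(as.data.frame(params))
  stopifnot(nrow(params) >= 1, nrow(pred_w1) == nrow(params),
            nrow(pred_w2) == nrow(params))
  n1 <- batch_nrmse(pred_w1, obs_w1)
  n2 <- batch_nrmse(pred_w2, obs_w2)
  out <- params
  out$nrmse_wave1 <- n1
  out$nrmse_wave2 <- n2
  out$nrmse_sum <- n1 + n2
  ord <- order(out$nrmse_sum)        # stable for ties
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

batch_nrmse <- function(pred, observed) {
  stopifnot(inherits(observed, "observed_wave"),
            ncol(pred) == length(observed$generations))
  if (any(observed$mean == 0))
    stop("zero mean observed copy number at some generation")
  total <- numeric(nrow(pred))
  for (g in seq_along(observed$generations)) {
    sq <- 0
    for (r in seq_len(ncol(observed$obs)))
      sq <- sq + (pred[, g] - observed$obs[g, r])^2
    total <- total + sqrt(sq / ncol(observed$obs)) / observed$mean[g]
  }
  total
}

#' Parameter and DFE-metric ranges over the top-k combinations
#'
#' Min/max of every model parameter and of the DFE summary metrics across
#' the `k` best-ranked combinations, alongside the rank-1 values.
#'
#' @param ranked Output of [rank_parameters()].
#' @param k Number of top combinations (default 100).
#' @param cfg An [efficacy_config()] for the DFE metrics.
#' @return A tibble with columns `metric`, `best`, `min`, `max`.
#' @export
top_k_ranges <- function(ranked, k = 100, cfg = efficacy_config()) {
  stopifnot(k >= 1, k <= nrow(ranked))
  top <- ranked[seq_len(k), , drop = FALSE]
  met <- top_metrics(top, cfg)
  cols <- c(intersect(names(param_bounds("extended")), names(met)),
            "mean_abs_s", "p95_abs_s", "neutral_fraction",
            "effective_mean_abs_s", "nrmse_sum")
  tibble::tibble(
    metric = cols,
    best = vapply(cols, function(cl) met[[cl]][1], numeric(1)),
    min = vapply(cols, function(cl) min(met[[cl]]), numeric(1)),
    max = vapply(cols, function(cl) max(met[[cl]]), numeric(1))
  )
}

# attach DFE summary metrics to fit-result rows
top_metrics <- function(top, cfg) {
  top$mean_abs_s <- dfe_mean_vec(top$alpha, top$beta)
  top$p95_abs_s <- qbeta(0.95, top$alpha, top$beta)
  top$neutral_fraction <- pbeta(cfg$threshold, top$alpha, top$beta)
  top$effective_mean_abs_s <- mapply(function(a, b)
    effective_mean(a, b, cfg), top$alpha, top$beta)
  top
}

dfe_mean_vec <- function(alpha, beta) alpha / (alpha + beta)

#' Group ranked combinations by mean selection efficacy
#'
#' Partitions the fit results into the "effective" and "effectively
#' neutral" groups by [classify_efficacy()] applied to each row's DFE, and
#' summarizes each group by its best combination (lowest `nrmse_sum`), that
#' combination's overall rank, and the within-group top-`k` ranges.
#'
#' @param ranked Output of [rank_parameters()].
#' @param cfg An [efficacy_config()].
#' @param k Top combinations per group for the ranges.
#' @return Named list (`effective`, `effectively_neutral`); each present
#'   group holds `best` (one-row tibble), `best_rank`, `n`, `ranges`.
#'   Empty groups are reported as `NULL`.
#' @export
group_by_efficacy <- function(ranked, cfg = efficacy_config(), k = 100) {
  grp <- ifelse(dfe_mean_vec(ranked$alpha, ranked$beta) > cfg$threshold,
                "effective", "effectively_neutral")
  out <- list(effective = NULL, effectively_neutral = NULL)
  for (g in names(out)) {
    sub <- ranked[grp == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    out[[g]] <- list(
      best = sub[1, , drop = FALSE],
      best_rank = sub$rank[1],
      n = nrow(sub),
      ranges = top_k_ranges(sub, k = min(k, nrow(sub)), cfg = cfg)
    )
  }
  out
}

#' Effective transposition rate from exponential copy-number growth
#'
#' Under unimpeded copy-and-paste growth, `CN_t = CN_0 * (1 + u')^t`;
#' inverting gives the per-generation effective rate
#' `u' = (CN_t / CN_0)^(1/t) - 1`.
#'
#' @param cn0 Copy number at generation 0 (> 0).
#' @param cnt Copy number at generation `t` (> 0).
#' @param t Number of generations (>= 1).
#' @return A one-row tibble: `u_prime`, `cn0`, `cnt`, `t`.
#' @export
#' @examples
#' estimate_effective_rate(1, 2, 10)$u_prime  # ~0.0718
estimate_effective_rate <- function(cn0, cnt, t) {
  stopifnot(t >= 1)
  if (cn0 <= 0 || cnt <= 0) stop("copy numbers must be positive")
  tibble::tibble(u_prime = (cnt / cn0)^(1 / t) - 1, cn0 = cn0, cnt = cnt,
                 t = t)
}

#' Read / write copy-number trajectory tables
#'
#' Plain TSV with columns `wave`, `replicate`, `generation`, `copy_number`.
#'
#' @param path File path.
#' @param df Data frame to write.
#' @return `read_trajectories` returns a tibble; `write_trajectories` its
#'   path, invisibly.
#' @export
read_trajectories <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t",
                               colClasses = c("integer", "integer",
                                              "integer", "numeric")))
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(df, path) {
  stopifnot(all(c("wave", "replicate", "generation", "copy_number")
                %in% names(df)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
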