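#' Selection-efficacy configuration
#'
#' Whether purifying selection on an insertion can overcome drift is judged
#' against the threshold `|s| = 1 / (2 * h * Ne)`: at co-dominance
#' (`h = 0.5`) this is the classic `|s| * Ne <= 1` criterion for effective
#' neutrality.
#'
#' @param Ne Effective population size (default 221; 442 for the robustness
#'   setting).
#' @param h Dominance coefficient.
#' @return An `efficacy_config` list with the derived `threshold`.
#' @export
#' @examples
#' efficacy_config()$threshold  # 1/221
efficacy_config <- function(Ne = 221, h = 0.5) {
  stopifnot(Ne > 0, h > 0)
  structure(list(Ne = Ne, h = h, threshold = 1 / (2 * h * Ne)),
            class = "efficacy_config")
}

check_shapes <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive")
}

#' Mean |s| of the Beta DFE
#'
#' `E(|s|) = alpha / (alpha + beta)`.
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @return Mean magnitude of the selection coefficient.
#' @export
#' @examples
#' dfe_mean(0.461, 10.743)  # ~0.041
dfe_mean <- function(alpha, beta) {
  check_shapes(alpha, beta)
  alpha / (alpha + beta)
}

#' Quantile of |s| under the Beta DFE
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @param q Probability in (0, 1).
#' @return The q-quantile of |s|.
#' @export
#' @examples
#' dfe_quantile(0.461, 10.743, 0.95)  # ~0.16
dfe_quantile <- function(alpha, beta, q) {
  check_shapes(alpha, beta)
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)")
  qbeta(q, alpha, beta)
}

#' Fraction of effectively neutral new insertions
#'
#' The Beta(alpha, beta) CDF evaluated at the drift threshold
#' `1 / (2 * h * Ne)`: the probability that a new insertion outside piRNA
#' clusters has too small an effect for selection to overcome drift.
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @param cfg An [efficacy_config()].
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' neutral_fraction(0.461, 10.743)  # ~0.273
neutral_fraction <- function(alpha, beta, cfg = efficacy_config()) {
  check_shapes(alpha, beta)
  pbeta(cfg$threshold, alpha, beta)
}

#' Mean |s| among insertions selection can act on
#'
#' Conditional mean `E(|s| | |s| > threshold)` of the Beta DFE above the
#' drift threshold, computed by numerical integration of the truncated
#' density (relative tolerance 1e-6).
#'
#' @inheritParams neutral_fraction
#' @return Conditional mean; always >= [dfe_mean()].
#' @export
#' @examples
#' effective_mean(0.461, 10.743)  # ~0.056
effective_mean <- function(alpha, beta, cfg = efficacy_config()) {
  check_shapes(alpha, beta)
  thr <- cfg$threshold
  tail_mass <- 1 - pbeta(thr, alpha, beta)
  if (tail_mass <= 0)
    stop("all DFE mass lies below the drift threshold; conditional mean undefined")
  num <- integrate(function(x) x * dbeta(x, alpha, beta), lower = thr,
                   upper = 1, rel.tol = 1e-6)$value
  num / tail_mass
}

#' Classify a DFE by mean selection efficacy
#'
#' A parameter combination is grouped as `"effective"` when the mean
#' insertion is visible to selection, i.e. `2 * h * mean|s| * Ne > 1`
#' (identical to `mean|s| * Ne > 1` at co-dominance), else
#' `"effectively_neutral"`.
#'
#' @inheritParams neutral_fraction
#' @return `"effective"` or `"effectively_neutral"`.
#' @export
#' @examples
#' classify_efficacy(0.461, 10.743)  # effective
#' classify_efficacy(0.065, 15.696)  # effectively_neutral
classify_efficacy <- function(alpha, beta, cfg = efficacy_config()) {
  if (dfe_mean(alpha, beta) > cfg$threshold) "effective"
  else "effectively_neutral"
}

#' Sample selection coefficients from the DFE
#'
#' Draws `|s| ~ Beta(alpha, beta)` and returns `-|s|` (purifying selection
#' only; no beneficial tail).
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @param n Number of draws.
#' @return Numeric vector of selection coefficients in `[-1, 0]`.
#' @export
sample_s <- function(alpha, beta, n) {
  check_shapes(alpha, beta)
  stopifnot(n >= 1)
  -rbeta(n, alpha, beta)
}

#' Full DFE summary for one parameter combination
#'
#' The four headline metrics plus the efficacy group.
#'
#' @inheritParams neutral_fraction
#' @return A one-row tibble: `mean_abs_s`, `p95_abs_s`, `neutral_fraction`,
#'   `effective_mean_abs_s`, `efficacy_group`.
#' @export
#' @examples
#' dfe_summary(0.461, 10.743)
dfe_summary <- function(alpha, beta, cfg = efficacy_config()) {
  tibble::tibble(
    alpha = alpha, beta = beta,
    mean_abs_s = dfe_mean(alpha, beta),
    p95_abs_s = dfe_quantile(alpha, beta, 0.95),
    neutral_fraction = neutral_fraction(alpha, beta, cfg),
    effective_mean_abs_s = effective_mean(alpha, beta, cfg),
    efficacy_group = classify_efficacy(alpha, beta, cfg)
  )
}

#' @importFrom stats dbeta
NULL
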