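#' Latin hypercube design over the model parameter space
#'
#' Draws `n` points with the Latin-hypercube property (exactly one point per
#' equal-width stratum in every dimension) and rescales them to the supplied
#' bounds. Uses R's RNG (seed with `set.seed()`).
#'
#' @param n Number of design points.
#' @param bounds Named list of `c(lo, hi)` per dimension, e.g.
#'   [param_bounds()].
#' @return An `n x d` matrix with `bounds` attached as attribute `"bounds"`.
#' @export
#' @examples
#' set.seed(1)
#' head(lhs_sample(10))
lhs_sample <- function(n, bounds = param_bounds("basic")) {
  stopifnot(n >= 1, length(bounds) >= 1)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!(hi > lo))) stop("degenerate bounds: need lo < hi per dimension")
  U <- lhs::randomLHS(n, length(bounds))
  X <- sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  colnames(X) <- names(bounds)
  attr(X, "bounds") <- bounds
  X
}

#' Simulate surrogate training targets for a design
#'
#' For each design point, runs the individual-based simulator `n_reps` times
#' for the given wave and records the replicate-mean copy number at the six
#' evolved generations (the surrogate tasks).
#'
#' @param design Design matrix from [lhs_sample()] (columns named after the
#'   model parameters; `h`/`v` columns optional).
#' @param wave A [wave_config()] or wave id.
#' @param n_reps Replicates per design point.
#' @param seed Master seed; per-point and per-replicate seeds are derived
#'   from it.
#' @return A `gp_dataset`: list with `X` (inputs), `Y` (n x 6 targets),
#'   `generations`, `wave_id`, `bounds`.
#' @export
build_training_set <- function(design, wave, n_reps = 20, seed = 1) {
  wv <- if (inherits(wave, "wave_config")) wave else wave_config(wave)
  bounds <- attr(design, "bounds")
  if (is.null(bounds)) stop("design must carry a 'bounds' attribute")
  gens <- wv$evolved_generations
  n <- nrow(design)
  Y <- matrix(NA_real_, n, length(gens))
  set.seed(seed)
  point_seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    p <- row_params(design[i, ])
    Y[i, ] <- replicate_mean(p, wv, n_reps = n_reps, seed = point_seeds[i],
                             record = gens)$copy_number
  }
  colnames(Y) <- gens
  structure(list(X = design, Y = Y, generations = gens,
                 wave_id = wv$wave_id, bounds = bounds),
            class = "gp_dataset")
}

# one design row -> model_params (h, v optional columns)
row_params <- function(x) {
  model_params(x[["p_carrier"]], x[["f_regulatory"]], x[["u"]],
               x[["alpha"]], x[["beta"]],
               h = if ("h" %in% names(x)) x[["h"]] else 0.5,
               v = if ("v" %in% names(x)) x[["v"]] else 0,
               bounds = NULL)
}

#' Training configuration for the multi-task GP
#'
#' Defaults are a desk-scale preset (10 rounds of 20 Adam iterations). The
#' full-scale preset used for production runs is 40 rounds of 50 iterations
#' at the same learning rate.
#'
#' @param rounds Training rounds; a model snapshot is saved after each.
#' @param iters_per_round Adam iterations per round.
#' @param learning_rate Adam step size.
#' @param jitter Diagonal jitter added to the joint covariance.
#' @return A `gp_config` list.
#' @export
gp_config <- function(rounds = 10, iters_per_round = 20,
                      learning_rate = 0.01, jitter = 1e-6) {
  stopifnot(rounds >= 1, iters_per_round >= 1, learning_rate > 0, jitter > 0)
  structure(list(rounds = rounds, iters_per_round = iters_per_round,
                 learning_rate = learning_rate, jitter = jitter),
            class = "gp_config")
}

# ---- multi-task GP internals ---------------------------------------------
#
# Joint covariance over (input, task) pairs:
#   k((x,t),(x',t')) = k_rbf(x,x') * K_task[t,t'],   K_task = w w^T + s2 I
# With inputs normalized to the unit cube and targets divided by a single
# global scale, the prior mean stays 0 on the original copy-number scale.
# The Kronecker structure Kx (x) Kt is exploited through separate
# eigendecompositions for O(n^3 + T^3) likelihood evaluations.

unpack_theta <- function(theta, d, nt) {
  list(log_ls = theta[seq_len(d)],
       log_os = theta[d + 1],
       omega = theta[d + 1 + seq_len(nt)],
       log_s2 = theta[d + nt + 2],
       log_noise = theta[d + nt + 3])
}

sq_dist <- function(A, B, ls) {
  A <- sweep(A, 2, ls, "/"); B <- sweep(B, 2, ls, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# eigendecomposition of the unit-outputscale RBF kernel
eig_input <- function(Xn, log_ls, Ys) {
  K <- exp(-0.5 * sq_dist(Xn, Xn, exp(log_ls)))
  e <- eigen(K, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors,
       Qx = crossprod(e$vectors, Ys))
}

eig_task <- function(omega, s2) {
  Kt <- tcrossprod(omega) + diag(s2, length(omega))
  e <- eigen(Kt, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, Kt = Kt)
}

# negative log marginal likelihood given precomputed input eigensystem;
# iid observation noise adds to every joint eigenvalue exactly under the
# Kronecker structure
nlml_core <- function(lam_x, Qx, omega, log_s2, log_noise, jitter) {
  et <- eig_task(omega, exp(log_s2))
  Q <- Qx %*% et$vectors
  D <- outer(lam_x, et$values) + exp(log_noise) + jitter
  0.5 * (sum(Q^2 / D) + sum(log(D)) + length(D) * log(2 * pi))
}

nlml_theta <- function(theta, d, nt, Xn, Ys, jitter) {
  th <- unpack_theta(theta, d, nt)
  ei <- eig_input(Xn, th$log_ls, Ys)
  nlml_core(exp(th$log_os) * ei$values, ei$Qx, th$omega, th$log_s2,
            th$log_noise, jitter)
}

# central-difference gradient, reusing the input eigensystem for every
# parameter that leaves the input kernel shape unchanged
nlml_grad <- function(theta, d, nt, Xn, Ys, jitter, eps = 1e-4) {
  th <- unpack_theta(theta, d, nt)
  g <- numeric(length(theta))
  # lengthscales: full recompute
  for (k in seq_len(d)) {
    for (sgn in c(1, -1)) {
      tp <- theta; tp[k] <- tp[k] + sgn * eps
      g[k] <- g[k] + sgn * nlml_theta(tp, d, nt, Xn, Ys, jitter)
    }
    g[k] <- g[k] / (2 * eps)
  }
  ei <- eig_input(Xn, th$log_ls, Ys)
  f_of <- function(log_os, omega, log_s2, log_noise = th$log_noise)
    nlml_core(exp(log_os) * ei$values, ei$Qx, omega, log_s2, log_noise,
              jitter)
  g[d + 1] <- (f_of(th$log_os + eps, th$omega, th$log_s2) -
               f_of(th$log_os - eps, th$omega, th$log_s2)) / (2 * eps)
  for (k in seq_len(nt)) {
    op <- th$omega; op[k] <- op[k] + eps
    om <- th$omega; om[k] <- om[k] - eps
    g[d + 1 + k] <- (f_of(th$log_os, op, th$log_s2) -
                     f_of(th$log_os, om, th$log_s2)) / (2 * eps)
  }
  g[d + nt + 2] <- (f_of(th$log_os, th$omega, th$log_s2 + eps) -
                    f_of(th$log_os, th$omega, th$log_s2 - eps)) / (2 * eps)
  g[d + nt + 3] <- (f_of(th$log_os, th$omega, th$log_s2, th$log_noise + eps) -
                    f_of(th$log_os, th$omega, th$log_s2,
                         th$log_noise - eps)) / (2 * eps)
  g
}

#' Train the multi-task GP surrogate
#'
#' Fits a six-task Gaussian process with a product kernel
#' `k_input(x, x') * k_task(t, t')`: an RBF input kernel with per-dimension
#' (ARD) lengthscales and a rank-1 task kernel `K_task = w w^T + s2 I`.
#' The constant mean is 0 copies, and an iid observation-noise variance
#' absorbs the Monte-Carlo error of the replicate-mean training targets.
#' Hyperparameters (lengthscales, output scale, task weights `w`, task
#' variance `s2`, noise variance) are fit by maximizing the log marginal
#' likelihood with Adam. After every round a snapshot is saved and
#' scored on the validation set; the snapshot with the lowest validation
#' RMSE is selected.
#'
#' @param train A `gp_dataset` from [build_training_set()].
#' @param validation Optional `gp_dataset` used for snapshot selection;
#'   without it the final snapshot is used.
#' @param config A [gp_config()].
#' @return An `mtgp` model object.
#' @export
train_gp <- function(train, validation = NULL, config = gp_config()) {
  stopifnot(inherits(train, "gp_dataset"))
  X <- train$X; Y <- train$Y
  if (nrow(X) < 2) stop("need at least 2 training points")
  bounds <- train$bounds
  d <- ncol(X); nt <- ncol(Y)
  Xn <- normalize_inputs(X, bounds)
  y_scale <- sd(as.numeric(Y)); if (!is.finite(y_scale) || y_scale <= 0) y_scale <- 1
  Ys <- Y / y_scale

  theta <- c(rep(log(0.5), d), log(1), rep(0.5, nt), log(0.1), log(0.005))
  gp <- structure(list(theta = theta, d = d, n_tasks = nt, bounds = bounds,
                       generations = train$generations,
                       wave_id = train$wave_id, x_names = colnames(X),
                       y_scale = y_scale, Xn = Xn, Ys = Ys, X = X, Y = Y,
                       config = config), class = "mtgp")

  m <- v <- numeric(length(theta)); b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  lr <- config$learning_rate; jit <- config$jitter
  snapshots <- list(); val_rmse <- numeric(0); train_nlml <- numeric(0)
  it <- 0
  for (round in seq_len(config$rounds)) {
    for (k in seq_len(config$iters_per_round)) {
      it <- it + 1
      g <- nlml_grad(theta, d, nt, Xn, Ys, jit)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      theta <- theta - lr * (m / (1 - b1^it)) /
        (sqrt(v / (1 - b2^it)) + epsa)
    }
    snapshots[[round]] <- theta
    train_nlml[round] <- nlml_theta(theta, d, nt, Xn, Ys, jit)
    if (!is.null(validation)) {
      gp$theta <- theta
      gp <- gp_finalize(gp)
      pr <- gp_predict(gp, validation$X)
      val_rmse[round] <- sqrt(mean((pr - validation$Y)^2))
    }
  }
  selected <- if (length(val_rmse)) which.min(val_rmse) else length(snapshots)
  gp$theta <- snapshots[[selected]]
  gp$snapshots <- snapshots
  gp$val_rmse <- if (length(val_rmse)) val_rmse else NULL
  gp$train_nlml <- train_nlml
  gp$selected <- selected
  gp_finalize(gp)
}

normalize_inputs <- function(X, bounds) {
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  sweep(sweep(X, 2, lo, "-"), 2, hi - lo, "/")
}

# precompute everything prediction needs for the current theta
gp_finalize <- function(gp) {
  th <- unpack_theta(gp$theta, gp$d, gp$n_tasks)
  ei <- eig_input(gp$Xn, th$log_ls, gp$Ys)
  et <- eig_task(th$omega, exp(th$log_s2))
  lam_x <- exp(th$log_os) * ei$values
  D <- outer(lam_x, et$values) + exp(th$log_noise) + gp$config$jitter
  A <- (crossprod(ei$vectors, gp$Ys) %*% et$vectors) / D
  gp$alpha_mat <- ei$vectors %*% A %*% t(et$vectors)
  gp$Kt <- et$Kt
  gp$eig <- list(Ux = ei$vectors, lam_x = lam_x,
                 Ut = et$vectors, lam_t = et$values)
  gp$hyper <- th
  gp
}

#' Predict copy-number trajectories with a trained surrogate
#'
#' Posterior-mean prediction of the six task outputs (mean copies per
#' haploid genome at the wave's evolved generations) for a batch of
#' parameter combinations. Points outside the training bounds trigger an
#' extrapolation warning but are still predicted.
#'
#' @param gp A trained `mtgp` from [train_gp()].
#' @param X Matrix (or single row) of parameter values, columns as in
#'   training.
#' @param se Also return predictive standard deviations (slower; intended
#'   for small batches).
#' @return `n x 6` matrix of predicted copy numbers (columns named by
#'   generation); with `se = TRUE`, a list with `mean` and `sd`.
#' @export
gp_predict <- function(gp, X, se = FALSE) {
  stopifnot(inherits(gp, "mtgp"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, gp$x_names))
  X <- as.matrix(X[, gp$x_names, drop = FALSE])
  Xn <- normalize_inputs(X, gp$bounds)
  if (any(Xn < -1e-9 | Xn > 1 + 1e-9))
    warning("some inputs lie outside the training bounds (extrapolation)")
  th <- gp$hyper
  Ks <- exp(th$log_os) * exp(-0.5 * sq_dist(Xn, gp$Xn, exp(th$log_ls)))
  mu <- (Ks %*% gp$alpha_mat %*% gp$Kt) * gp$y_scale
  colnames(mu) <- gp$generations
  if (!se) return(mu)
  sdm <- matrix(NA_real_, nrow(X), gp$n_tasks)
  U2 <- crossprod(gp$eig$Ux, t(Ks))              # n_train x m
  D <- outer(gp$eig$lam_x, gp$eig$lam_t) + exp(gp$hyper$log_noise) +
    gp$config$jitter
  for (i in seq_len(nrow(X))) {
    u2 <- U2[, i]^2
    for (t in seq_len(gp$n_tasks)) {
      w2 <- gp$eig$Ut[t, ]^2
      varr <- exp(th$log_os) * gp$Kt[t, t] - sum((u2 %o% w2) / D)
      sdm[i, t] <- sqrt(max(varr, 0)) * gp$y_scale
    }
  }
  colnames(sdm) <- gp$generations
  list(mean = mu, sd = sdm)
}

#' Held-out surrogate accuracy as per-task normalized RMSE
#'
#' RMSE between predictions and simulated targets per task (generation),
#' divided by that task's mean observed value.
#'
#' @param gp A trained `mtgp`.
#' @param test A `gp_dataset` with targets.
#' @return Named numeric vector of per-task NRMSE.
#' @export
gp_evaluate <- function(gp, test) {
  stopifnot(inherits(test, "gp_dataset"))
  pred <- gp_predict(gp, test$X)
  task_nrmse(pred, test$Y)
}

#' Per-task normalized RMSE between two target matrices
#'
#' @param pred,obs Matrices of identical shape (points x tasks).
#' @return Named numeric vector: per-column RMSE / column mean of `obs`.
#' @export
task_nrmse <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  mo <- colMeans(obs)
  if (any(mo == 0)) stop("zero mean observed value in a task")
  out <- sqrt(colMeans((pred - obs)^2)) / mo
  names(out) <- colnames(obs)
  out
}

#' @export
print.mtgp <- function(x, ...) {
  cat(sprintf("Multi-task GP surrogate (wave %d): %d training points, %d tasks\n",
              x$wave_id, nrow(x$X), x$n_tasks))
  cat(sprintf("  selected snapshot %d of %d", x$selected, length(x$snapshots)))
  if (!is.null(x$val_rmse))
    cat(sprintf(" (validation RMSE %.3f)", x$val_rmse[x$selected]))
  cat("\n  lengthscales:", paste(sprintf("%.2f", exp(x$hyper$log_ls)),
                                 collapse = " "), "\n")
  cat(sprintf("  observation noise sd: %.3f (scaled units)\n",
              sqrt(exp(x$hyper$log_noise))))
  invisible(x)
}

#' Save / load a trained surrogate
#'
#' Stores the full model state (hyperparameters, training data, normalizers)
#' in a single file.
#'
#' @param gp A trained `mtgp`.
#' @param path File path.
#' @return `read_gp` returns the `mtgp`; `write_gp` its path, invisibly.
#' @export
write_gp <- function(gp, path) { saveRDS(gp, path); invisible(path) }

#' @rdname write_gp
#' @export
read_gp <- function(path) readRDS(path)
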