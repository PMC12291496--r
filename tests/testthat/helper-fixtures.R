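# shared fixtures for fast tests

fig_params <- function() model_params(0.189, 0.014, 0.277, 0.484, 10.327)

# neutral configuration: no clusters, no selection, copy-and-paste
neutral_params <- function(u = 0.2) {
  model_params(p_carrier = 0.3, f_regulatory = 0, u = u, alpha = 0,
               beta = 10, bounds = NULL)
}

# deterministic toy response for GP unit tests: smooth in x, linear in task
toy_dataset <- function(n, bounds = list(x1 = c(0, 1), x2 = c(0, 2)),
                        n_tasks = 6) {
  X <- lhs_sample(n, bounds)
  base <- 2 * X[, 1]^2 + X[, 2]
  Y <- outer(base, seq(0.5, 3, length.out = n_tasks))
  structure(list(X = X, Y = Y, generations = seq_len(n_tasks), wave_id = 1,
                 bounds = bounds), class = "gp_dataset")
}

# observed_wave built from a matrix of replicate trajectories
observed_from_matrix <- function(obs, wave) {
  wv <- wave_config(wave)
  gens <- wv$evolved_generations
  df <- data.frame(
    replicate = rep(seq_len(ncol(obs)), each = length(gens)),
    generation = rep(gens, ncol(obs)),
    copy_number = as.numeric(obs)
  )
  observed_wave(df, wv)
}
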