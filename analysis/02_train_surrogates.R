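#!/usr/bin/env Rscript

# Step 2: train one multi-task Gaussian-process surrogate per wave.
#
# Draws Latin-hypercube designs over the basic parameter space, runs the
# individual-based simulator at each design point, and fits a multi-task GP
# to the replicate-mean copy numbers at the six evolved sampling generations.
# Writes the fitted surrogates and their held-out accuracy to results/.
#
# Sizes are desk-scale defaults chosen to finish on a single CPU in minutes;
# pass larger values for production runs:
#   Rscript analysis/02_train_surrogates.R [n_train] [n_val] [n_reps] [seed]

suppressPackageStartupMessages(library(teinvade))

args <- commandArgs(trailingOnly = TRUE)
n_train <- if (length(args) >= 1) as.integer(args[1]) else 150L
n_val   <- if (length(args) >= 2) as.integer(args[2]) else 50L
n_reps  <- if (length(args) >= 3) as.integer(args[3]) else 8L
seed    <- if (length(args) >= 4) as.integer(args[4]) else 20240602L

dir.create("results", showWarnings = FALSE)
set.seed(seed)
seeds <- sample.int(.Machine$integer.max, 4)

for (wave in 1:2) {
  cat("== wave", wave, "==\n")
  set.seed(seeds[wave])
  X_train <- lhs_sample(n_train)
  X_val <- lhs_sample(n_val)
  t0 <- Sys.time()
  train <- build_training_set(X_train, wave, n_reps = n_reps,
                              seed = seeds[wave])
  val <- build_training_set(X_val, wave, n_reps = n_reps,
                            seed = seeds[wave + 2])
  cat("  simulated", n_train + n_val, "design points in",
      round(as.numeric(Sys.time() - t0, units = "mins"), 1), "min\n")
  gp <- train_gp(train, val, gp_config())
  ev <- gp_evaluate(gp, val)
  cat("  held-out per-generation NRMSE:",
      paste(signif(ev, 3), collapse = " "), "\n")
  write_gp(gp, sprintf("results/gp_wave%d.rds", wave))
}
cat("wrote results/gp_wave1.rds, results/gp_wave2.rds\n")
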