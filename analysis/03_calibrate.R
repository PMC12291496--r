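#!/usr/bin/env Rscript

# Step 3: calibrate the model against the pseudo-empirical data.
#
# Evaluates both wave surrogates over a dense Latin-hypercube grid, ranks
# parameter combinations by summed normalized RMSE against the observed
# trajectories, and writes the ranked table, the top-100 parameter ranges,
# and the efficacy-group summaries to results/.
#
# Usage: Rscript analysis/03_calibrate.R [n_grid] [seed]

suppressPackageStartupMessages(library(teinvade))

args <- commandArgs(trailingOnly = TRUE)
n_grid <- if (length(args) >= 1) as.integer(args[1]) else 10000L
seed   <- if (length(args) >= 2) as.integer(args[2]) else 20240603L

obs <- read_trajectories("results/pseudo_empirical.tsv")
ow1 <- observed_wave(obs, 1)
ow2 <- observed_wave(obs, 2)
gp1 <- read_gp("results/gp_wave1.rds")
gp2 <- read_gp("results/gp_wave2.rds")

set.seed(seed)
grid <- lhs_sample(n_grid)
pred1 <- gp_predict(gp1, grid)
pred2 <- gp_predict(gp2, grid)

ranked <- rank_parameters(as.data.frame(grid), pred1, pred2, ow1, ow2)
write.table(ranked, "results/ranked_parameters.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cfg <- efficacy_config()
ranges <- top_k_ranges(ranked, k = 100, cfg)
write.table(ranges, "results/top100_ranges.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

groups <- group_by_efficacy(ranked, cfg, k = 100)
cat("best-fitting combination:\n")
print(ranked[1, c("p_carrier", "f_regulatory", "u", "alpha", "beta",
                  "nrmse_sum")])
for (g in names(groups)) {
  if (is.null(groups[[g]])) next
  cat(sprintf("%s group: n = %d, best rank = %d\n",
              g, groups[[g]]$n, groups[[g]]$best_rank))
}
saveRDS(groups, "results/efficacy_groups.rds")
cat("wrote results/ranked_parameters.tsv, top100_ranges.tsv,",
    "efficacy_groups.rds\n")
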