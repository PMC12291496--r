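test_that("NRMSE matches hand-computed values and its invariances", {
  # one generation, obs = (1, 2, 3), pred = 2 -> sqrt(2/3)/2
  obs1 <- matrix(c(1, 2, 3), nrow = 1)
  ow <- structure(list(wave_id = 1, generations = 10, obs = obs1,
                       mean = 2), class = "observed_wave")
  expect_equal(nrmse_wave(2, ow), sqrt(2 / 3) / 2)
  # perfect predictions of identical replicates -> 0
  obs <- matrix(rep(c(5, 9, 13, 15, 15, 16), 3), ncol = 3)
  oww <- observed_from_matrix(obs, 1)
  expect_equal(nrmse_wave(obs[, 1], oww), 0)
  # invariance under common rescaling
  pred <- obs[, 1] + 0.7
  ow10 <- observed_from_matrix(10 * obs, 1)
  expect_equal(nrmse_wave(pred, oww), nrmse_wave(10 * pred, ow10))
  # additivity over generations: computed per generation then summed
  per_gen <- sapply(1:6, function(g)
    sqrt(mean((pred[g] - obs[g, ])^2)) / mean(obs[g, ]))
  expect_equal(nrmse_wave(pred, oww), sum(per_gen))
  # zero observed mean signals
  obs0 <- obs; obs0[2, ] <- 0
  expect_error(nrmse_wave(pred, observed_from_matrix(obs0, 1)), "zero mean")
})

test_that("observed-wave tables parse and exclude generation 0", {
  df <- expand.grid(replicate = 1:3,
                    generation = wave_config(1)$recorded_generations)
  df$copy_number <- runif(nrow(df), 1, 20)
  df$wave <- 1L
  ow <- observed_wave(df, 1)
  expect_equal(rownames(ow$obs), as.character(c(10, 20, 30, 40, 50, 60)))
  expect_equal(ncol(ow$obs), 3)
  # missing generations are reported
  expect_error(observed_wave(df[df$generation != 30, ], 1), "missing")
})

test_that("parameter ranking orders by summed NRMSE with stable ties", {
  set.seed(3)
  obs <- matrix(rep(c(5, 9, 13, 15, 15, 16), 3), ncol = 3) +
    matrix(rnorm(18, 0, 0.5), ncol = 3)
  ow1 <- observed_from_matrix(obs, 1)
  ow2 <- observed_from_matrix(obs + 2, 2)
  params <- data.frame(p_carrier = c(0.2, 0.3, 0.25),
                       f_regulatory = 0.02, u = 0.3,
                       alpha = c(0.4, 0.01, 0.4), beta = 12)
  perfect1 <- matrix(rowMeans(obs), 3, 6, byrow = TRUE)
  perfect2 <- matrix(rowMeans(obs + 2), 3, 6, byrow = TRUE)
  pred1 <- perfect1; pred1[2, ] <- pred1[2, ] + 5; pred1[3, ] <- pred1[3, ] + 1
  ranked <- rank_parameters(params, pred1, perfect2, ow1, ow2)
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$p_carrier, c(0.2, 0.25, 0.3))  # best first
  expect_equal(ranked$nrmse_sum, ranked$nrmse_wave1 + ranked$nrmse_wave2)
  expect_true(!is.unsorted(ranked$nrmse_sum))
  # single combination gets rank 1
  single <- rank_parameters(params[1, ], pred1[1, , drop = FALSE],
                            perfect2[1, , drop = FALSE], ow1, ow2)
  expect_equal(single$rank, 1)
  # exact ties keep input order
  tied <- rank_parameters(params[c(1, 3), ], pred1[c(2, 2), ],
                          perfect2[c(1, 1), ], ow1, ow2)
  expect_equal(tied$p_carrier, c(0.2, 0.25))
})

test_that("top-k ranges bracket the best combination", {
  set.seed(4)
  n <- 30
  params <- data.frame(p_carrier = runif(n, 0.15, 0.5),
                       f_regulatory = runif(n, 0.01, 0.1),
                       u = runif(n, 0.15, 0.5),
                       alpha = runif(n, 0.1, 0.5),
                       beta = runif(n, 10, 20))
  obs <- matrix(rep(c(5, 9, 13, 15, 15, 16), 3), ncol = 3)
  ow1 <- observed_from_matrix(obs, 1); ow2 <- observed_from_matrix(obs, 2)
  pred <- matrix(runif(n * 6, 1, 20), n, 6)
  ranked <- rank_parameters(params, pred, pred, ow1, ow2)
  rg <- top_k_ranges(ranked, k = 10)
  expect_true(all(rg$min <= rg$best & rg$best <= rg$max))
  # k = 1 collapses ranges to the best point
  rg1 <- top_k_ranges(ranked, k = 1)
  expect_equal(rg1$min, rg1$max)
  expect_equal(rg1$best, rg1$min)
  expect_true(all(c("mean_abs_s", "neutral_fraction") %in% rg$metric))
})

test_that("efficacy grouping partitions and summarizes fit results", {
  set.seed(6)
  n <- 40
  params <- data.frame(p_carrier = runif(n, 0.15, 0.5),
                       f_regulatory = runif(n, 0.01, 0.1),
                       u = runif(n, 0.15, 0.5),
                       alpha = c(runif(n / 2, 0.3, 0.5),     # effective
                                 runif(n / 2, 0.001, 0.03)), # mostly neutral
                       beta = runif(n, 10, 20))
  obs <- matrix(rep(c(5, 9, 13, 15, 15, 16), 3), ncol = 3)
  ow1 <- observed_from_matrix(obs, 1); ow2 <- observed_from_matrix(obs, 2)
  pred <- matrix(runif(n * 6, 1, 20), n, 6)
  ranked <- rank_parameters(params, pred, pred, ow1, ow2)
  gr <- group_by_efficacy(ranked, efficacy_config(), k = 10)
  expect_false(is.null(gr$effective))
  expect_equal(gr$effective$n + gr$effectively_neutral$n, n)
  expect_equal(gr$effective$best$rank, gr$effective$best_rank)
  # the grouping criterion itself
  cls <- ifelse(ranked$alpha / (ranked$alpha + ranked$beta) * 221 > 1,
                "effective", "effectively_neutral")
  expect_equal(gr$effective$n, sum(cls == "effective"))
  # all-neutral input leaves the effective group absent
  pn <- params; pn$alpha <- 0.001
  rn <- rank_parameters(pn, pred, pred, ow1, ow2)
  gn <- group_by_efficacy(rn, efficacy_config())
  expect_null(gn$effective)
  expect_equal(gn$effectively_neutral$n, n)
})

test_that("effective transposition rate inverts exponential growth", {
  expect_equal(estimate_effective_rate(5, 5, 10)$u_prime, 0)
  expect_equal(estimate_effective_rate(1, 2, 10)$u_prime, 2^0.1 - 1)
  expect_equal(estimate_effective_rate(0.86, 0.86 * 1.2^10, 10)$u_prime, 0.2)
  expect_error(estimate_effective_rate(0, 5, 10), "positive")
})

test_that("trajectory tables round-trip through TSV", {
  df <- data.frame(wave = 1L, replicate = rep(1:2, each = 3),
                   generation = rep(c(0L, 10L, 20L), 2),
                   copy_number = c(0.9, 3.2, 14.1, 0.8, 3.5, 13.7))
  path <- tempfile(fileext = ".tsv")
  write_trajectories(df, path)
  back <- read_trajectories(path)
  expect_equal(as.data.frame(back), df)
  unlink(path)
})
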