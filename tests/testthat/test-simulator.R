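lay0 <- genome_layout(0)        # no clusters
p_fig <- NULL                   # populated lazily in tests

test_that("fitness is multiplicative with dominance", {
  expect_equal(population_fitness(make_individual()), 1)
  # one homozygous locus, s = -0.1 -> 1 + s
  ind <- make_individual(pos1 = 100, s1 = -0.1, pos2 = 100, s2 = -0.1)
  expect_equal(population_fitness(ind), 0.9)
  # two heterozygous loci, s = -0.1, h = 0.5 -> 0.95^2
  ind <- make_individual(pos1 = c(100, 5e6), s1 = c(-0.1, -0.1))
  expect_equal(population_fitness(ind, h = 0.5), 0.95^2)
  expect_equal(population_fitness(ind, h = 1), 0.9^2)
  expect_equal(population_fitness(ind, h = 0), 1)
  # lethal homozygote hits the fitness floor
  ind <- make_individual(pos1 = 100, s1 = -1, pos2 = 100, s2 = -1)
  expect_equal(population_fitness(ind), 1e-9)
})

test_that("transposition follows the trap model", {
  p <- model_params(0.3, 0.05, 0.3, 0.484, 10.327)
  lay <- genome_layout(p$f_regulatory)
  # u = 0: unchanged
  set.seed(1)
  ind <- make_individual(pos1 = c(1e6, 2e6), s1 = c(-0.01, -0.02))
  p0 <- p; p0$u <- 0
  expect_identical(transpose_individual(ind, p0, lay), ind)
  # a cluster insertion silences: zero new insertions even at u = 1
  sp <- cluster_spans(lay)
  sil <- make_individual(pos1 = sp$start[1] + 5, s1 = 0)
  p1 <- p; p1$u <- 1
  for (i in 1:50) expect_identical(transpose_individual(sil, p1, lay), sil)
})

test_that("transposition count matches the binomial expectation", {
  # 10 active copies at u = 0.3: mean 3 new copies per generation
  p <- model_params(0.3, 0, 0.3, 0, 10, bounds = NULL)
  ind <- make_individual(pos1 = seq(1e6, 5e7, length.out = 5),
                         s1 = numeric(5),
                         pos2 = seq(6e7, 9e7, length.out = 5),
                         s2 = numeric(5))
  set.seed(42)
  n_new <- replicate(1e4, {
    out <- transpose_individual(ind, p, lay0)
    nrow(out$h1) + nrow(out$h2) - 10
  })
  expect_lt(abs(mean(n_new) - 3), 3 * sd(n_new) / sqrt(length(n_new)))
  # with excision v = 1 every transposing copy moves: copy count conserved
  pv <- p; pv$v <- 1
  set.seed(43)
  n_tot <- replicate(200, {
    out <- transpose_individual(ind, pv, lay0)
    nrow(out$h1) + nrow(out$h2)
  })
  expect_true(all(n_tot == 10))
})

test_that("gametes recombine as a Poisson process and assort independently", {
  # recomb_rate = 0: each chromosome is one intact parental haplotype
  lay_nr <- genome_layout(0, recomb_rate = 0)
  ind <- make_individual(pos1 = c(1e6, 2e6, 3e6), s1 = numeric(3),
                         pos2 = c(1.5e6, 2.5e6), s2 = numeric(2))
  set.seed(5)
  for (i in 1:20) {
    g <- make_gamete(ind, lay_nr)
    expect_true(identical(g[, "pos"], ind$h1[, "pos"]) ||
                identical(g[, "pos"], ind$h2[, "pos"]))
  }
  # markers at opposite chromosome ends recombine when the crossover count
  # between them is odd: P = (1 - exp(-2 * 1.296)) / 2 under the Poisson
  # process with mean 32.4e6 * 4e-8 = 1.296 crossovers per chromosome
  set.seed(6)
  far <- make_individual(pos1 = c(1, 32.4e6 - 1), s1 = numeric(2))
  n_rec <- 0; n <- 4000
  for (i in seq_len(n)) {
    g <- make_gamete(far, genome_layout(0))
    if (nrow(g) == 1) n_rec <- n_rec + 1
  }
  p_odd <- (1 - exp(-2 * 1.296)) / 2
  expect_lt(abs(n_rec / n - p_odd), 3 * sqrt(p_odd * (1 - p_odd) / n))
  # two loci on different chromosomes co-inherit ~50% of the time
  set.seed(7)
  two <- make_individual(pos1 = c(1e6, 40e6), s1 = numeric(2))
  co <- replicate(1e4, {
    g <- make_gamete(two, genome_layout(0))
    nrow(g) %in% c(0, 2)
  })
  expect_lt(abs(mean(co) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("mean crossover count per chromosome matches rate x length", {
  # count breakpoints indirectly: a fully heterozygous parent with dense
  # markers lets us count switches between parental origins
  set.seed(8)
  pos <- seq(0, 32.4e6 - 1, length.out = 200)
  ind <- make_individual(pos1 = pos[c(TRUE, FALSE)], s1 = numeric(100),
                         pos2 = pos[c(FALSE, TRUE)], s2 = numeric(100))
  lay1 <- genome_layout(0, n_chromosomes = 1)
  switches <- replicate(2000, {
    g <- make_gamete(ind, lay1)
    src <- g[, "pos"] %in% ind$h1[, "pos"]  # origin of each marker
    sum(diff(src) != 0)
  })
  # observed switch count underestimates crossovers only via double events
  # between adjacent markers (~ negligible at this density)
  expect_lt(abs(mean(switches) - 1.296), 3 * sd(switches) / sqrt(2000) + 0.05)
})

test_that("neutral dynamics conserve and grow copy number as expected", {
  # u = 0, s = 0: Mendelian conservation of the replicate-mean CN
  set.seed(9)
  p0 <- neutral_params(u = 0)
  w <- wave_config(1)
  tr <- replicate_mean(p0, w, n_reps = 50, seed = 11, generations = 20,
                       record = c(0, 5, 10, 15, 20), keep_replicates = TRUE)
  reps <- attr(tr, "replicates")
  long <- data.frame(generation = rep(tr$generation, each = nrow(reps)),
                     copy_number = as.numeric(reps))
  fit <- lm(copy_number ~ generation, data = long)
  slope_se <- summary(fit)$coefficients["generation", "Std. Error"]
  expect_lt(abs(coef(fit)["generation"]), 3 * slope_se + 1e-3)
  # f_regulatory -> 0, s = 0, v = 0: E[CN_t] = CN_0 (1+u)^t
  p2 <- neutral_params(u = 0.2)
  tr2 <- replicate_mean(p2, w, n_reps = 50, seed = 12, generations = 10,
                        record = c(0, 5, 10), keep_replicates = TRUE)
  reps <- attr(tr2, "replicates")
  for (j in 2:3) {
    t <- c(0, 5, 10)[j]
    expected <- tr2$copy_number[1] * 1.2^t
    se <- sd(reps[, j]) / sqrt(nrow(reps))
    expect_lt(abs(tr2$copy_number[j] - expected), 3 * se)
  }
})

test_that("stronger purifying selection never speeds up the invasion", {
  # larger alpha at fixed beta = larger mean |s|; replicate-mean CN at the
  # horizon must not increase beyond Monte-Carlo noise
  w <- wave_config(1)
  alphas <- c(0.01, 0.2, 0.5)
  cn <- se <- numeric(3)
  for (i in seq_along(alphas)) {
    p <- model_params(0.189, 0.014, 0.277, alphas[i], 10.327)
    tr <- replicate_mean(p, w, n_reps = 50, seed = 700 + i,
                         generations = 30, record = c(0, 30),
                         keep_replicates = TRUE)
    reps <- attr(tr, "replicates")
    cn[i] <- tr$copy_number[2]
    se[i] <- sd(reps[, 2]) / sqrt(nrow(reps))
  }
  expect_lt(cn[2], cn[1] + 3 * sqrt(se[1]^2 + se[2]^2))
  expect_lt(cn[3], cn[2] + 3 * sqrt(se[2]^2 + se[3]^2))
})

test_that("trap silencing holds throughout a full run", {
  set.seed(31)
  p <- fig_params()
  lay <- genome_layout(p$f_regulatory)
  tr <- run_invasion(p, wave_config(1), generations = 15,
                     record = c(0, 15), return_population = TRUE)
  pop <- attr(tr, "population")
  sil <- is_silenced(pop)
  expect_gt(sum(sil), 0)
  # cluster insertions always have s = 0
  for (ind in unclass(pop)) {
    for (hp in c("h1", "h2")) {
      m <- ind[[hp]]
      if (nrow(m) == 0) next
      expect_true(all(m[in_cluster(m[, "pos"], lay), "s"] == 0))
      expect_true(all(m[, "s"] <= 0 & m[, "s"] >= -1))
    }
  }
  # silenced individuals never gain insertions, at any u
  p_hot <- p; p_hot$u <- 1
  for (ind in unclass(pop)[sil][1:min(20, sum(sil))]) {
    out <- transpose_individual(ind, p_hot, lay)
    expect_identical(out[c("h1", "h2")], ind[c("h1", "h2")])
  }
})

test_that("stepping a generation preserves census and outcrossing sanity", {
  set.seed(41)
  p <- fig_params()
  w <- wave_config(1)
  pop <- init_founders(p, w)
  nxt <- step_generation(pop, p, w)
  expect_length(nxt, w$census_n)
  # all-lethal population collapses
  lethal <- replicate(10, make_individual(pos1 = 1e6, s1 = -1,
                                          pos2 = 1e6, s2 = -1),
                      simplify = FALSE)
  pop0 <- structure(lethal, class = "population",
                    layout = genome_layout(0.01))
  expect_error(step_generation(pop0, p, w, fitness_floor = 0),
               "collapse")
})

test_that("replicate means are deterministic given the seed", {
  p <- fig_params()
  w <- wave_config(1)
  a <- replicate_mean(p, w, n_reps = 3, seed = 5, generations = 10,
                      record = c(0, 10))
  b <- replicate_mean(p, w, n_reps = 3, seed = 5, generations = 10,
                      record = c(0, 10))
  expect_identical(a, b)
  one <- replicate_mean(p, w, n_reps = 1, seed = 6, generations = 10,
                        record = c(0, 10))
  set.seed(6)
  s1 <- sample.int(.Machine$integer.max, 1)
  set.seed(s1)
  direct <- run_invasion(p, w, generations = 10, record = c(0, 10))
  expect_equal(one$copy_number, direct$copy_number)
})
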