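test_that("experiment_params validates its domain", {
  expect_error(experiment_params(n_lineages = 0), "n_lineages")
  expect_error(experiment_params(cells_per_well_range = c(0, 10)),
               "cells_per_well_range")
  expect_error(experiment_params(cells_per_well_range = c(3000, 400)),
               "cells_per_well_range")
  expect_error(experiment_params(p_adapt = 1.2), "p_adapt")
  expect_error(experiment_params(mutation_model = "spontaneous"))
})

test_that("induced model with p_induced = 0 yields no mutations", {
  p <- experiment_params(n_lineages = 20, mutation_model = "induced",
                         p_induced = 0, seed = 4)
  tab <- simulate_lineage(p)
  expect_gt(nrow(tab), 0)
  expect_true(all(is.na(tab$locus_id)))
  expect_true(all(tab$mutant_fraction == 0))
})

test_that("lineage table structure: unique colonies, adapted only, fraction rule", {
  p <- experiment_params(n_lineages = 30, mutation_model = "induced",
                         p_induced = 0.3, seed = 9)
  tab <- simulate_lineage(p)
  expect_true(all(tab$adapted))
  per <- split(tab$colony_id, tab$lineage_id)
  expect_true(all(vapply(per, anyDuplicated, integer(1)) == 0))
  # mutant_fraction > 0 iff a mutation is present, and exactly 2^(-g)
  mut <- !is.na(tab$locus_id)
  expect_true(all(tab$mutant_fraction[mut] > 0))
  expect_true(all(tab$mutant_fraction[!mut] == 0))
  expect_equal(tab$mutant_fraction[mut],
               2^(-tab$emergence_generation[mut]))
  expect_true(all(tab$emergence_generation[mut] %in% 0:2))
  # emergence generation 2 -> a quarter of the mature colony is mutant
  g2 <- tab$emergence_generation[mut] == 2
  expect_true(any(g2))
  expect_true(all(tab$mutant_fraction[mut][g2] == 0.25))
})

test_that("counter-based seeding: adding lineages never perturbs earlier ones", {
  p5 <- experiment_params(n_lineages = 5, seed = 12)
  p10 <- experiment_params(n_lineages = 10, seed = 12)
  t5 <- simulate_lineage(p5)
  t10 <- simulate_lineage(p10)
  expect_equal(as.data.frame(t5),
               as.data.frame(t10[t10$lineage_id <= 5, ]),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(simulate_lineage(p5)), as.data.frame(t5),
               ignore_attr = TRUE)
})

test_that("phase-I founder-mutation events match the division-count expectation", {
  # every one of the n - 1 divisions is an independent Bernoulli(mu) trial,
  # so the exact expectation (enumerating all division events) is mu*(n-1)
  mu <- 1e-3; n_cells <- 1000L; reps <- 10000L
  set.seed(100)
  events <- vapply(seq_len(reps), function(i)
    nrow(phase1_mutations(n_cells, mu)), numeric(1))
  expected <- mu * (n_cells - 1)
  mc_se <- sd(events) / sqrt(reps)
  expect_lt(abs(mean(events) - expected), 3 * mc_se)
  # capped synchronous tree: descendants are census/2^t
  set.seed(101)
  ev <- phase1_mutations(1024L, 0.05)
  expect_true(all(ev$descendants == 1024 / 2^ev$generation))
})

test_that("fluctuation summary: constant counts, errors, Poisson vs jackpot", {
  # constant one mutant colony per lineage -> variance-to-mean 0
  tab <- data.table::data.table(
    lineage_id = 1:6, colony_id = sprintf("L%03d.C01", 1:6), adapted = TRUE,
    locus_id = sprintf("m%d", 1:6), emergence_generation = 0L,
    mutant_fraction = 1)
  data.table::setattr(tab, "n_lineages", 6L)
  fs <- fluctuation_summary(tab)
  expect_equal(fs$variance_to_mean, 0)
  expect_equal(fs$fraction_lineages_with_mutant, 1)
  expect_error(fluctuation_summary(tab[1, ], n_lineages = 1), "single")
})

test_that("induced mutant colonies are exchangeable across lineages", {
  # randomized permutation p-values for the lineage-dispersion statistic are
  # exactly Uniform(0,1) when colonies are exchangeeable; Kolmogorov-Smirnov
  # against uniform at alpha = 0.01
  n_sim <- 1000L; n_perm <- 99L
  p <- experiment_params(n_lineages = 15, cells_per_well_range = c(800, 800),
                         p_adapt = 0.02, mutation_model = "induced",
                         p_induced = 0.1)
  set.seed(2024)
  pvals <- vapply(seq_len(n_sim), function(s) {
    tab <- simulate_lineage(p, seed = s)
    lin <- tab$lineage_id
    mut <- !is.na(tab$locus_id)
    stat <- function(flags) var(tabulate(lin[flags], nbins = 15))
    obs <- stat(mut)
    perm <- vapply(seq_len(n_perm), function(i) stat(sample(mut)), numeric(1))
    (sum(perm > obs) + runif(1) * (1 + sum(perm == obs))) / (n_perm + 1)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("pre-existing allele sharing across colonies grows with mu", {
  # descendants of one phase-I event carry an identical locus_id, so the
  # chance that two colonies of a lineage share an allele rises with mu
  share_rate <- function(mu) {
    p <- experiment_params(n_lineages = 10000, mutation_model = "preexisting",
                           cells_per_well_range = c(64, 64), p_adapt = 0.2,
                           mu_predivision = mu, seed = 77)
    tab <- simulate_lineage(p)
    mut <- tab[!is.na(tab$locus_id), ]
    if (nrow(mut) == 0) return(0)
    per_allele <- table(paste(mut$lineage_id, mut$locus_id))
    length(unique(sub(" .*", "", names(per_allele)[per_allele >= 2]))) / 10000
  }
  rates <- vapply(c(1e-4, 1e-3, 1e-2), share_rate, numeric(1))
  expect_true(all(rates > 0))
  expect_true(all(diff(rates) > 0))
})

test_that("simulated growth curves have the stated three-phase shape", {
  ts0 <- simulate_colony_growth(phase_params = list(noise_sd = 0, s2 = 0))
  idx <- ts0$t >= ts0$changepoints["t1"] & ts0$t <= ts0$changepoints["t2"]
  expect_equal(diff(range(ts0$area[idx])), 0)   # exactly flat plateau
  # defaults: arrest lasts 2-3 days
  arrest <- diff(unname(ts0$changepoints))
  expect_gte(arrest, 48); expect_lte(arrest, 72)
  expect_error(simulate_colony_growth(t_grid = c(0, 2, 2, 4)),
               "strictly increasing")
  expect_error(simulate_colony_growth(phase_params = list(t1 = 90, t2 = 50)),
               "changepoints")
})
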