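# Simulation of the 96-well lineage-separation experiment: one founder cell
# per well grows to a few hundred-thousand cells (phase I), the well census is
# spread on a selective plate, and a subset of the plated daughters found
# independently adapting colonies. Competing mutation-timing models:
#   * preexisting -- target-locus mutations arise during phase-I divisions and
#     are inherited by all descendants (Luria-Delbruck jackpots);
#   * induced     -- each adapted colony independently acquires a mutation at
#     growth resumption (Poisson-like across lineages);
#   * none        -- adaptation without any mutation.

#' Parameters for the lineage-separation experiment simulator
#'
#' @param n_lineages number of wells/lineages (default 56, the number of
#'   lineages grown in the original assay).
#' @param cells_per_well_range integer interval for the phase-I well census;
#'   default `c(400, 3000)`, the observed census range at the end of phase I.
#' @param p_adapt probability that a plated cell founds an adapted colony.
#'   Default 0.014, calibrated so that a census around 1357 cells yields on
#'   average ~19 adapted colonies per lineage.
#' @param mutation_model one of `"preexisting"`, `"induced"`, `"none"`.
#' @param mu_predivision per-division probability of a target-locus mutation
#'   during phase-I growth (pre-plating). Default 1e-6, the order of a
#'   per-gene per-division spontaneous rate in yeast.
#' @param p_induced probability that an adapting cell acquires a target-locus
#'   mutation at growth resumption. Default 0.042 (the observed fraction of
#'   adapted colonies carrying a hotspot-locus mutation).
#' @param locus_fraction fraction of the genome occupied by the target locus
#'   (default 1e-4).
#' @param post_adaptation_divisions upper bound of the emergence-generation
#'   support under the induced model; emergence is uniform on
#'   `{0, ..., post_adaptation_divisions}` (default 2, i.e. the first 1-3
#'   generations of adapted growth).
#' @param seed default RNG seed carried with the parameter set.
#' @return an object of class `experiment_params`
#' @export
experiment_params <- function(n_lineages = 56L,
                              cells_per_well_range = c(400L, 3000L),
                              p_adapt = 0.014,
                              mutation_model = c("induced", "preexisting",
                                                 "none"),
                              mu_predivision = 1e-6,
                              p_induced = 0.042,
                              locus_fraction = 1e-4,
                              post_adaptation_divisions = 2L,
                              seed = 1L) {
  mutation_model <- match.arg(mutation_model)
  assert_count(n_lineages, "n_lineages", min = 1)
  if (length(cells_per_well_range) != 2L ||
      any(cells_per_well_range < 1) || any(cells_per_well_range > 1e6) ||
      cells_per_well_range[1] > cells_per_well_range[2])
    stop("'cells_per_well_range' must be an increasing interval within [1, 1e6]",
         call. = FALSE)
  assert_prob(p_adapt, "p_adapt")
  assert_prob(mu_predivision, "mu_predivision")
  assert_prob(p_induced, "p_induced")
  assert_prob(locus_fraction, "locus_fraction")
  assert_count(post_adaptation_divisions, "post_adaptation_divisions", min = 0)
  structure(list(
    n_lineages = as.integer(n_lineages),
    cells_per_well_range = as.integer(cells_per_well_range),
    p_adapt = p_adapt,
    mutation_model = mutation_model,
    mu_predivision = mu_predivision,
    p_induced = p_induced,
    locus_fraction = locus_fraction,
    post_adaptation_divisions = as.integer(post_adaptation_divisions),
    seed = as.integer(seed)
  ), class = "experiment_params")
}

#' Phase-I founder mutations on a capped synchronous division tree
#'
#' The well census grows by synchronous binary doubling 1, 2, 4, ... capped at
#' `n_cells`; every division independently mutates the target locus with
#' probability `mu`. A mutation at a division completing generation `t` is
#' inherited by all descendants of the newborn cell, counted as
#' `round(n_cells / census_t)` cells of the final census (exact when the
#' census is a power of two). Total divisions are exactly `n_cells - 1`, so
#' the expected number of founder-mutation events per well is
#' `mu * (n_cells - 1)`.
#'
#' @param n_cells final well census (>= 1)
#' @param mu per-division mutation probability of the locus
#' @return data.frame with one row per mutation event: `generation`,
#'   `descendants` (mutant cells at plating). Zero rows when no event occurs.
#' @export
phase1_mutations <- function(n_cells, mu) {
  n_cells <- assert_count(n_cells, "n_cells", min = 1)
  assert_prob(mu, "mu")
  gen <- integer(0); desc <- integer(0)
  census_prev <- 1
  t <- 0L
  while (census_prev < n_cells) {
    t <- t + 1L
    census <- min(2 * census_prev, n_cells)
    divisions <- census - census_prev
    k <- stats::rbinom(1L, divisions, mu)
    if (k > 0) {
      gen <- c(gen, rep.int(t, k))
      desc <- c(desc, rep.int(max(1L, as.integer(round(n_cells / census))), k))
    }
    census_prev <- census
  }
  data.frame(generation = gen, descendants = desc)
}

#' Simulate the lineage-separation experiment
#'
#' One well per lineage: the census is drawn uniformly from
#' `cells_per_well_range`, phase-I mutations are placed on the division tree
#' (preexisting model only), the census is plated, and each plated cell founds
#' an adapted colony with probability `p_adapt`. Under the induced model each
#' adapted colony independently carries a new mutation with probability
#' `p_induced`, with emergence generation uniform on
#' `{0, ..., post_adaptation_divisions}` and within-colony mutant fraction
#' `2^(-g)` under deterministic doubling. Under the preexisting model colonies
#' founded by mutant cells carry the founder allele clonally (fraction 1);
#' colonies descending from the same phase-I event share an identical
#' `locus_id`.
#'
#' Randomness is split per lineage from `seed` with a counter-based scheme, so
#' increasing `n_lineages` reproduces earlier lineages exactly.
#'
#' @param params an [experiment_params()] object
#' @param seed RNG seed; defaults to `params$seed`
#' @return a `data.table` of class `lineage_table` with one row per
#'   colony-mutation pair (mutation fields `NA`/0 for mutation-free colonies):
#'   `lineage_id`, `colony_id`, `adapted`, `locus_id`, `emergence_generation`,
#'   `mutant_fraction`. Attributes: `n_lineages`, `mutation_model`.
#' @export
simulate_lineage <- function(params, seed = params$seed) {
  if (!inherits(params, "experiment_params"))
    params <- do.call(experiment_params, as.list(params))
  rng_lineage <- split_seed(seed, seq_len(params$n_lineages))
  rows <- vector("list", params$n_lineages)
  for (i in seq_len(params$n_lineages)) {
    rows[[i]] <- local_seed(rng_lineage[i], {
      simulate_one_well(params, i)
    })
  }
  tab <- data.table::rbindlist(rows)
  data.table::setattr(tab, "n_lineages", params$n_lineages)
  data.table::setattr(tab, "mutation_model", params$mutation_model)
  data.table::setattr(tab, "class", c("lineage_table", class(tab)))
  tab[]
}

# one well -> rows for its adapted colonies (internal; RNG already seeded)
simulate_one_well <- function(params, lineage_id) {
  rng <- params$cells_per_well_range
  n_cells <- if (rng[1] == rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)
  empty <- data.table::data.table(
    lineage_id = integer(0), colony_id = character(0), adapted = logical(0),
    locus_id = character(0), emergence_generation = integer(0),
    mutant_fraction = numeric(0))

  if (params$mutation_model == "preexisting") {
    ev <- phase1_mutations(n_cells, params$mu_predivision)
    n_mut_cells <- if (nrow(ev)) pmin(ev$descendants, n_cells) else integer(0)
    n_wt <- max(0L, n_cells - sum(n_mut_cells))
    k_wt <- stats::rbinom(1L, n_wt, params$p_adapt)
    k_mut <- if (nrow(ev))
      stats::rbinom(nrow(ev), n_mut_cells, params$p_adapt) else integer(0)
    n_col <- k_wt + sum(k_mut)
    if (n_col == 0) return(empty)
    locus <- c(rep(NA_character_, k_wt),
               rep(sprintf("L%03d.pre%02d", lineage_id, seq_len(nrow(ev))),
                   times = k_mut))
    gen <- ifelse(is.na(locus), NA_integer_, 0L)
    frac <- ifelse(is.na(locus), 0, 1)
  } else if (params$mutation_model == "induced") {
    n_col <- stats::rbinom(1L, n_cells, params$p_adapt)
    if (n_col == 0) return(empty)
    mutated <- stats::runif(n_col) < params$p_induced
    gen <- rep(NA_integer_, n_col)
    gen[mutated] <- sample(0:params$post_adaptation_divisions,
                           sum(mutated), replace = TRUE)
    locus <- rep(NA_character_, n_col)
    locus[mutated] <- sprintf("L%03d.ind%02d", lineage_id,
                              seq_len(sum(mutated)))
    frac <- ifelse(mutated, 2^(-gen), 0)
  } else {                                   # none
    n_col <- stats::rbinom(1L, n_cells, params$p_adapt)
    if (n_col == 0) return(empty)
    locus <- rep(NA_character_, n_col)
    gen <- rep(NA_integer_, n_col)
    frac <- rep(0, n_col)
  }
  data.table::data.table(
    lineage_id = lineage_id,
    colony_id = sprintf("L%03d.C%02d", lineage_id, seq_len(n_col)),
    adapted = TRUE,
    locus_id = locus,
    emergence_generation = gen,
    mutant_fraction = frac)
}

#' Fluctuation summary of mutant colonies per lineage
#'
#' Tabulates the number of mutation-carrying colonies per lineage (lineages
#' without any adapted colony count as zero) and computes the
#' variance-to-mean ratio with the unbiased variance estimator. Under the
#' induced model the counts are Poisson-like (ratio near 1); pre-existing
#' phase-I mutations produce jackpot lineages and overdispersion (ratio well
#' above 1), the classical fluctuation-test discrimination.
#'
#' @param table a `lineage_table` from [simulate_lineage()]
#' @param n_lineages total number of lineages; defaults to the table's
#'   `n_lineages` attribute
#' @return list of class `fluctuation_summary`: `counts` (mutant colonies per
#'   lineage), `histogram`, `variance_to_mean`,
#'   `fraction_lineages_with_mutant`, `n_lineages`
#' @export
fluctuation_summary <- function(table, n_lineages = attr(table, "n_lineages")) {
  if (is.null(n_lineages))
    n_lineages <- length(unique(table$lineage_id))
  if (nrow(table) == 0 && n_lineages < 1)
    stop("empty lineage table", call. = FALSE)
  if (n_lineages < 2)
    stop("variance-to-mean undefined for a single lineage", call. = FALSE)
  counts <- integer(n_lineages)
  if (nrow(table)) {
    mut <- table[!is.na(table$locus_id), ]
    if (nrow(mut)) {
      per <- mut[, list(k = length(unique(colony_id))), by = "lineage_id"]
      counts[per$lineage_id] <- per$k
    }
  }
  m <- mean(counts)
  vmr <- if (m == 0) {
    warning("no mutant colonies: variance-to-mean undefined")
    NA_real_
  } else stats::var(counts) / m
  structure(list(
    counts = counts,
    histogram = table(factor(counts, levels = 0:max(counts))),
    variance_to_mean = vmr,
    fraction_lineages_with_mutant = mean(counts > 0),
    n_lineages = n_lineages
  ), class = "fluctuation_summary")
}

#' Simulate a three-phase colony growth curve
#'
#' Colony area over time is piecewise log-linear with two changepoints:
#' exponential micro-colony growth (phase I, slope `s1`), division arrest
#' with almost no area increase (phase II, slope `s2`), and slow resumed
#' growth (phase III, slope `s3`), with multiplicative log-normal noise.
#' Defaults place the arrest between 24 h and 96 h post plating, i.e. an
#' arrest lasting about 3 days, with resumption thereafter.
#'
#' @param t_grid strictly increasing observation times in hours
#'   (default every 2 h over 0-240 h, the imaging cadence)
#' @param phase_params list with `t1`, `t2` (changepoints, hours),
#'   `s1`, `s2`, `s3` (log-area slopes per hour), `log_area0` (log pixels at
#'   t = 0) and `noise_sd` (sd of multiplicative log-normal noise)
#' @param seed RNG seed
#' @return list of class `area_time_series`: `t`, `area`, `changepoints`,
#'   `slopes`, `noise_sd`
#' @export
simulate_colony_growth <- function(t_grid = seq(0, 240, by = 2),
                                   phase_params = list(),
                                   seed = NULL) {
  p <- utils::modifyList(list(t1 = 24, t2 = 96, s1 = 0.15, s2 = 0.002,
                              s3 = 0.05, log_area0 = log(50),
                              noise_sd = 0.05), phase_params)
  if (any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  if (!(0 < p$t1 && p$t1 < p$t2 && p$t2 < max(t_grid)))
    stop("changepoints must satisfy 0 < t1 < t2 < max(t_grid)", call. = FALSE)
  if (p$s1 <= 0 || p$s3 <= 0)
    stop("phase I and III slopes must be positive on the log-area scale",
         call. = FALSE)
  la <- p$log_area0 + p$s1 * pmin(t_grid, p$t1) +
    p$s2 * pmax(0, pmin(t_grid, p$t2) - p$t1) +
    p$s3 * pmax(0, t_grid - p$t2)
  if (p$noise_sd > 0)
    la <- la + local_seed(seed, stats::rnorm(length(t_grid), 0, p$noise_sd))
  structure(list(t = t_grid, area = exp(la),
                 changepoints = c(t1 = p$t1, t2 = p$t2),
                 slopes = c(s1 = p$s1, s2 = p$s2, s3 = p$s3),
                 noise_sd = p$noise_sd),
            class = "area_time_series")
}
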