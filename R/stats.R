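# Incidence statistics: per-base mutation incidence by functional class,
# per-strain mutation counts, exact locus-enrichment test, and emergence
# timing from within-colony mutant fractions.

# class groups used for incidence accounting: indels are pooled regardless
# of frame consequence, SNPs keep their functional class
incidence_class <- function(calls) {
  ifelse(calls$type %in% c("ins", "del"), "indel", calls$functional_class)
}

#' Per-base mutation incidence table
#'
#' For each mutation class c with count m_c over S included strains and a
#' nuclear genome of G bp, the per-base incidence is r_c = m_c / (S * G):
#' mutations per base per sequenced genome (not per generation). Also
#' reports the total incidence r_all and the mean mutations per genome.
#'
#' @param calls mutation-call table (nuclear, included strains only); needs
#'   `type` and `functional_class` columns. May have zero rows.
#' @param n_strains number of included strains S
#' @param genome_length nuclear genome length G in bp (default 12071326, the
#'   S. cerevisiae S288c R64 nuclear assembly)
#' @return list of class `incidence_table`: `by_class` (data.table: class,
#'   count, incidence), `total_count`, `r_all`, `per_genome_mean`,
#'   `n_strains`, `genome_length`
#' @export
incidence_table <- function(calls, n_strains,
                            genome_length = 12071326) {
  assert_count(n_strains, "n_strains", min = 1)
  assert_pos(genome_length, "genome_length")
  classes <- c("intergenic", "synonymous", "missense", "nonsense", "indel")
  cnt <- if (nrow(calls)) table(factor(incidence_class(calls),
                                       levels = classes))
         else table(factor(character(0), levels = classes))
  denom <- n_strains * genome_length
  by_class <- data.table::data.table(
    class = classes,
    count = as.integer(cnt),
    incidence = as.numeric(cnt) / denom)
  structure(list(by_class = by_class,
                 total_count = sum(by_class$count),
                 r_all = sum(by_class$count) / denom,
                 per_genome_mean = sum(by_class$count) / n_strains,
                 n_strains = as.integer(n_strains),
                 genome_length = genome_length),
            class = "incidence_table")
}

#' Mutations-per-strain distribution
#'
#' Histogram of the number of mutations per strain, including strains with
#' zero mutations. The histogram mass equals the number of strains and its
#' weighted sum equals the total mutation count.
#'
#' @param calls mutation-call table with a `strain_id` column
#' @param strain_ids all included strains (zero-mutation strains too)
#' @return list of class `per_strain_distribution`: `per_strain` (named
#'   counts), `histogram` (table: mutations-per-strain value -> strains),
#'   `n_strains`, `total_mutations`
#' @export
per_strain_distribution <- function(calls, strain_ids) {
  if (nrow(calls) && !all(calls$strain_id %in% strain_ids))
    stop("call with strain_id outside 'strain_ids'", call. = FALSE)
  per <- table(factor(calls$strain_id, levels = strain_ids))
  hist <- table(factor(as.integer(per), levels = 0:max(per)))
  structure(list(per_strain = per,
                 histogram = hist,
                 n_strains = length(strain_ids),
                 total_mutations = sum(per)),
            class = "per_strain_distribution")
}

#' Exact upper Poisson tail by direct summation
#'
#' P(X >= k) for X ~ Poisson(mean): the tail terms are summed directly,
#' starting from term_k = exp(-mean + k log(mean) - log k!) and using the
#' stable recurrence term_{i+1} = term_i * mean / (i + 1) until the running
#' sum converges. No normal approximation, no complement-of-CDF
#' cancellation.
#'
#' @param k observed count (integer >= 0)
#' @param mean Poisson mean (>= 0)
#' @return tail probability in [0, 1]
#' @export
poisson_tail <- function(k, mean) {
  k <- assert_count(k, "k", min = 0)
  if (mean < 0) stop("'mean' must be >= 0", call. = FALSE)
  if (k == 0) return(1)
  if (mean == 0) return(0)
  term <- exp(-mean + k * log(mean) - lgamma(k + 1))
  acc <- term
  i <- k
  repeat {
    i <- i + 1
    term <- term * mean / i
    acc <- acc + term
    if (term <= acc * 1e-17 && i > mean) break
  }
  min(1, acc)
}

#' Locus-enrichment test for a mutational hotspot
#'
#' Under a uniform-mutagenesis null, the expected number of colonies with a
#' mutation in a locus occupying fraction f = locus_len / genome_len of the
#' genome is `n_colonies * per_genome_rate * f`. The p-value is the exact
#' Poisson tail P(X >= observed_k); a binomial alternative (each colony
#' mutated in the locus with probability `per_genome_rate * f`) is available
#' via `method = "binomial"`.
#'
#' @param observed_k colonies observed with a mutation in the locus
#' @param n_colonies colonies screened
#' @param locus_len locus length (bp)
#' @param genome_len genome length (bp)
#' @param per_genome_rate expected mutations per genome under the null
#'   (default 0.82, the self-calibrated empirical rate)
#' @param method "poisson" (default, exact tail) or "binomial"
#' @return list of class `enrichment_result`: `observed_k`, `n_colonies`,
#'   `observed_incidence`, `locus_fraction`, `expected`, `p_value`, `method`
#' @export
locus_enrichment <- function(observed_k, n_colonies, locus_len, genome_len,
                             per_genome_rate = 0.82,
                             method = c("poisson", "binomial")) {
  method <- match.arg(method)
  observed_k <- assert_count(observed_k, "observed_k", min = 0)
  n_colonies <- assert_count(n_colonies, "n_colonies", min = 1)
  assert_pos(genome_len, "genome_len")
  if (locus_len > genome_len)
    stop("'locus_len' must be <= 'genome_len'", call. = FALSE)
  if (per_genome_rate < 0)
    stop("'per_genome_rate' must be >= 0", call. = FALSE)
  f <- locus_len / genome_len
  expected <- n_colonies * per_genome_rate * f
  if (expected == 0 && observed_k > 0) {
    warning("expected count is 0 with observed_k > 0: p-value reported as 0")
    p <- 0
  } else if (method == "poisson") {
    p <- poisson_tail(observed_k, expected)
  } else {
    p_one <- per_genome_rate * f
    p <- sum(stats::dbinom(observed_k:n_colonies, n_colonies, p_one))
  }
  structure(list(observed_k = observed_k, n_colonies = n_colonies,
                 observed_incidence = observed_k / n_colonies,
                 locus_fraction = f, expected = expected,
                 p_value = p, method = method),
            class = "enrichment_result")
}

#' Mutation emergence generation from the within-colony mutant fraction
#'
#' Under deterministic doubling, a mutation arising in generation g of
#' adapted growth ends up in a fraction 2^(-g) of the mature colony: g = 0
#' (the first adapted cell) gives fraction 1; g = 2 (one of the four cells
#' after two divisions) gives 1/4. Consensus (Sanger-style) sequencing
#' detects the mutation only when the fraction is at least 0.25.
#'
#' @param mutant_fraction fraction of mutant cells in the colony, in (0, 1]
#' @return list of class `emergence_estimate`: `mutant_fraction`,
#'   `generation`, `detectable_by_consensus`
#' @export
emergence_generation <- function(mutant_fraction) {
  if (!is.numeric(mutant_fraction) || length(mutant_fraction) != 1L ||
      is.na(mutant_fraction) || mutant_fraction <= 0 || mutant_fraction > 1)
    stop("'mutant_fraction' must lie in (0, 1]", call. = FALSE)
  g <- as.integer(round(-log2(mutant_fraction)))
  structure(list(mutant_fraction = mutant_fraction,
                 generation = g,
                 detectable_by_consensus = mutant_fraction >= 0.25),
            class = "emergence_estimate")
}

#' Summary statistics for well-census plating controls
#'
#' Mean, unbiased standard deviation and standard error of the mean for
#' colony counts from control platings (e.g. the 16-well census control).
#' When `sd` and `n` are supplied instead of raw counts, the standard error
#' is computed directly as sd / sqrt(n).
#'
#' @param counts numeric vector of colony counts, or NULL
#' @param sd,n alternative input: printed standard deviation and well count
#' @return list: `mean` (NA when unavailable), `sd`, `n`, `se`
#' @export
census_summary <- function(counts = NULL, sd = NULL, n = NULL) {
  if (!is.null(counts)) {
    n <- length(counts)
    m <- mean(counts)
    s <- stats::sd(counts)
  } else {
    if (is.null(sd) || is.null(n))
      stop("supply either 'counts' or both 'sd' and 'n'", call. = FALSE)
    m <- NA_real_; s <- sd
  }
  list(mean = m, sd = s, n = n, se = s / sqrt(n))
}
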