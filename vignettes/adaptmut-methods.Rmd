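---
title: "Models and methods behind adaptmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adaptmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adaptmut)
```

# The biological setting

`adaptmut` analyses mutation data from haploid yeast lineages adapting to a
severe regulatory challenge: an essential gene placed under the exclusive
control of a repressed regulatory system, so that growth requires a
regulatory (or genetic) resolution rather than a pre-encoded pathway. The
experimental design the package models separates a lineage into its
daughter cells *before* adaptation: a single founder cell grows in a well to
a census of a few hundred to a few thousand cells (phase I), the well is
spread on a selective plate, and every colony that later appears is an
*independently adapting sub-lineage* of the same founder. Because all
daughters are physically isolated before growth resumes, the genotypes of
the adapted colonies discriminate between two mutation-timing models:

* **pre-existing**: mutations arise during phase-I divisions and are
  inherited by whole sub-trees of descendants. The number of mutant colonies
  per lineage is then heavy-tailed ("jackpots", the classical
  Luria–Delbrück signature) and identical alleles recur within a lineage.
* **induced**: each adapting cell independently acquires a mutation at the
  time growth resumes. Mutant colonies are then near-Poisson across
  lineages and alleles do not recur.

The package implements both simulators, the variant-calling and
coverage-analysis stack used to read out the genomes, and the incidence,
enrichment and timing statistics used to interpret them.

# Experiment simulator

## Phase-I division tree

Phase-I growth is a *synchronous binary division tree*: the census doubles
each generation (1, 2, 4, …), capped at the drawn well census
`n`. Every division mutates the target locus independently with probability
`mu_predivision`; because a capped tree has exactly `n − 1` division events,
the expected number of founder-mutation events per well is exactly
`mu_predivision × (n − 1)` — this closed form is the oracle for the
simulator's unit tests. A mutation completing generation `t` is inherited by
`round(n / 2^t)` of the plated cells (exact when `n` is a power of two).
This keeps the per-well cost at `O(log n)` instead of `O(n)`; the
approximation ignores the (rare at these rates) nesting of two events on
one path, so a colony carries at most one pre-existing allele.

## Adaptation and emergence timing

Each plated cell founds an adapted colony with probability `p_adapt`
(default 0.014, calibrated so a census of about 1357 cells yields on
average ~19 adapted colonies per lineage, the anchor reported for the
original assay; both numbers are calibration anchors, not fitted values).
Under the induced model a colony acquires a mutation with probability
`p_induced` (default 0.042, the observed hotspot-locus incidence among
adapted colonies) and its emergence generation is uniform on {0, 1, 2}:
consensus (Sanger-style) sequencing only detects mutations that arose in
the first one to three generations of adapted growth, and uniform is the
least-informative distribution on that support. Under deterministic
doubling, a mutation of generation `g` ends at fraction `2^(−g)` of the
mature colony; `emergence_generation()` inverts this rule and applies the
25%-consensus detectability threshold.

## Fluctuation summary

`fluctuation_summary()` reports the variance-to-mean ratio (unbiased
variance) of mutant colonies per lineage. One analysis choice matters and
is deliberate: when the well census is drawn from the wide default range
(400–3000 cells), the colony count per lineage is overdispersed by census
variation alone, which would contaminate the Poisson band for the induced
model. The discrimination test therefore fixes the census at 1357 cells
(the measured mean census), so the ratio measures mutation independence and
not census spread. Defaults for data generation remain 400–3000.

# Synthetic genomes and count tables

The reference is a toy haploid genome (default three nuclear chromosomes of
50/40/30 kb plus a 6 kb mitochondrial chromosome that all analyses
exclude), with non-overlapping full-CDS genes of length divisible by three
on alternating strands. Coordinates are 1-based inclusive everywhere.

Counts are simulated per position, not per read: depth is
Poisson(`mean_depth`), doubled on duplicated chromosomes (haploid
background), and base counts are multinomial with the reference base at
`1 − error_rate` and errors split evenly over the three other bases. A
planted SNP with colony fraction `f` moves `f (1 − error_rate)` of the mass
to the alternative base, so sub-clonal mixtures are representable.
Insertion/deletion evidence is a separate pair of counters anchored at the
base left of the event, with a background indel-error rate of
`error_rate / 10` (indel miscalls are rarer than base miscalls on short
reads). What this generator does **not** emulate: alignment artefacts,
mapping bias, GC bias, quality-score structure, or real repeat content — a
green round-trip test establishes that the caller inverts *this* generative
model, not that it would be competitive on real pileups.

# Variant calling

The ancestor consensus (majority) base defines the local reference at each
position. A SNP is called when the strain's best non-reference base reaches
`min_alt_fraction_strain` (default 0.8), the ancestor carries at most
`max_alt_fraction_ancestor` (default 0.05) of that base, and both depths
reach `min_depth` (default 5). The two fraction thresholds are this
package's own defaults: clonal haploid colonies should be near-fixed, 0.8
tolerates sequencing error plus modest heterogeneity, and genuinely mixed
colonies are handled separately by the 25% minor-allele rule
(`detect_mixed_colony()`). Sites below `min_depth` are *no-calls*, logged
separately from reference-matching sites. Strain-level QC requires depth
≥ 5 on ≥ 80% of nuclear positions.

Indel candidates use the same fraction logic on the evidence counters and
are then filtered for low-complexity context: a homopolymer run of ≥ 6 bp
containing the event, or a perfect 2–3-mer tandem repeat spanning ≥ 12 bp.
The rule is explicit and configurable because the original analysis only
states that uncertain indels in low-complexity and repetitive sequence were
removed after manual inspection; the boundary-overlap refusal
(`needs_review`) mirrors the manual queue.

Functional classification translates the affected codon strand-aware under
the standard genetic code; `protein_pos = ceiling(cds_offset / 3)`. The
test suite checks 1000 random coding SNPs against an independent oracle
that rebuilds and translates the entire mutant CDS.

# Aneuploidy detection

`sample_windows()` draws 500 random 10-kb windows genome-wide, allocated to
chromosomes proportionally to length with a floor of 20 windows per
chromosome so short chromosomes remain callable. `call_duplications()`
compares the median window depth of each chromosome with the median over
all other chromosomes and calls a duplication when the ratio falls in
[1.75, 2.25], targeting the 2× coverage of a duplication on a haploid
background. Medians make the ratio robust to focal outliers and the
verdict scale-invariant.

**Limitation**: with only three toy chromosomes, duplicating the largest
one makes it the dominant contributor to every other chromosome's
denominator; a 2× event on the largest chromosome plus one more can then
mask the second event. The 16-chromosome real genome does not have this
failure mode; the test fixtures avoid planting a duplication on the largest
toy chromosome together with another.

# Statistics

* **Per-base incidence** (`incidence_table()`): `r_c = m_c / (S × G)` for
  class counts `m_c` over `S` included strains and nuclear genome length
  `G`. `G` is never printed in the source analysis and is therefore an
  explicit parameter; the default 12,071,326 bp is the S288c R64 nuclear
  length implied by back-calculation from the published incidences.
  Rounding to 2–3 significant figures happens only at presentation.
* **Locus enrichment** (`locus_enrichment()`): the uniform-mutagenesis null
  expects `n_colonies × per_genome_rate × locus_fraction` mutant colonies;
  the p-value is the exact upper Poisson tail, computed by direct summation
  of tail terms from `term_k = exp(−m + k log m − log k!)` with the stable
  recurrence `term_{i+1} = term_i · m/(i+1)` — no normal approximation and
  no 1-minus-CDF cancellation, giving ≤ 1e−12 absolute error against a
  high-precision oracle on the tested grid. The original analysis argues by
  incidence comparison without naming a test; the exact Poisson test is
  this package's formalization, with a binomial alternative behind
  `method = "binomial"`. `per_genome_rate` defaults to the self-calibrated
  empirical 0.82 mutations per genome.
* **Emergence timing** (`emergence_generation()`): `g = round(−log2 f)`,
  detectable by consensus sequencing iff `f ≥ 0.25`.

# Growth-phase segmentation

`segment_phases()` fits a continuous piecewise-linear model with two
changepoints to log(area) by exhaustive search over all changepoint pairs
on the observation grid (ties broken toward the earliest pair), the
simplest model matching the qualitative three-phase description of colony
adaptation; the source analysis describes no fitting procedure at all. The
three-phase verdict uses `s_min = 0.02 h⁻¹` (visible growth in phases I and
III) and `s_flat = 0.005 h⁻¹` (phase II is "almost no increase"); both are
exposed. Each segment must contain at least `min_segment_points = 4`
observations. `colony_area()` counts the largest 4-connected component of a
binary mask, ignoring detached debris; it exists for synthetic masks only.

# Numerical and reproducibility choices

* One master seed, split per stage / strain / lineage with a counter-based
  multiplicative scheme; adding lineages or strains never perturbs earlier
  ones, and pipeline reruns are byte-identical.
* Exhaustive changepoint search uses `.lm.fit` per pair; noiseless
  three-phase curves are recovered exactly on grid points (SSE 0 at the
  true pair), which is the oracle for the zero-noise test.
* Configuration is JSON (no YAML parser in the supported dependency set);
  unknown keys fail fast, naming the key.
* Degenerate inputs are errors, not silent coercions: single-lineage
  variance, all-mitochondrial QC tracks, zero-median coverage denominators,
  non-monotone time grids, fractions outside (0, 1].

# What the tests establish

The acceptance suite reproduces the published desk-level arithmetic
(incidence table, per-genome mean, hotspot incidence, emergence fraction,
control standard error) exactly at printed precision, and establishes
*property-level* correctness of the pipeline on synthetic data: planted
SNP recovery at sensitivity 1.0/FDR 0 (depth 30, error 0.005), duplication
sensitivity/specificity 1.0 on a 20-strain panel with 5 aneuploid strains,
variance-to-mean discrimination between the mutation-timing models, and
changepoint recovery within ±2 grid steps in ≥ 95% of noisy curves. None of
this validates performance on real sequencing data, which is outside the
package's scope.
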