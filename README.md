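# adaptmut

Mutation analysis for haploid yeast lineages adapting to an unforeseen
regulatory challenge.

When an essential gene is rewired under the control of a repressed
regulatory system, cells face a challenge no pre-existing variant solves.
A lineage-separation design — one founder cell per well, grown to a few
hundred–thousand cells, then spread so every later colony is an
independently adapting sub-lineage — lets the *timing* of the mutations be
read from the genomes of the adapted colonies. `adaptmut` provides the full
analysis stack for this design, exercised end-to-end on synthetic data:

* **Experiment simulator** — the 96-well lineage-separation assay under
  *pre-existing* (Luria–Delbrück jackpot) vs *induced* (Poisson-like)
  mutation models, with known ground truth; fluctuation summary via the
  variance-to-mean ratio of mutant colonies per lineage.
* **Synthetic genomics** — toy haploid reference + gene model, planted
  SNPs/indels, per-position nucleotide count tables and coverage tracks
  (Poisson depth, uniform base-error model), whole-chromosome duplications
  as 2× coverage.
* **Variant calling** — ancestor-vs-adapted frequency comparison at each
  position (alt fraction ≥ 0.8 in the strain, ≤ 0.05 in the ancestor,
  depth ≥ 5 in both), coverage QC (depth ≥ 5 over ≥ 80% of the nuclear
  genome), low-complexity indel filtering, strand-aware functional
  classification (synonymous / missense / nonsense / frameshift /
  inframe), and mixed-colony detection (minor allele ≥ 25%).
* **Aneuploidy** — 500 random 10-kb windows; per-chromosome median window
  depth over the median of the rest; duplicated when the ratio is in
  [1.75, 2.25].
* **Statistics** — per-base mutation incidence r_c = m_c / (S·G) by class,
  mutations-per-strain histogram, exact Poisson locus-enrichment test
  P(X ≥ k | m = n·λ·f) by direct tail summation, and emergence timing
  g = round(−log₂ f) from within-colony mutant fractions (a mutation in
  one of the four cells after two divisions leaves ¼ of the colony mutant).
* **Growth phases** — exhaustive-search continuous piecewise-linear
  segmentation of log colony area into exponential growth / arrest /
  resumed growth, plus a largest-component pixel area for binary masks.

## Worked example

```r
library(adaptmut)

# published mutation spectrum: 18 SNPs + 5 indels over 28 adapted genomes
calls <- data.table::data.table(
  strain_id = "x", type = rep(c("snp", "del"), c(18, 5)),
  functional_class = rep(c("intergenic", "synonymous", "missense",
                           "nonsense", "frameshift"), c(4, 4, 7, 3, 5)))
inc <- incidence_table(calls, n_strains = 28, genome_length = 12071326)
inc$by_class
#>         class count    incidence
#> 1: intergenic     4 1.183442e-08
#> 2: synonymous     4 1.183442e-08
#> 3:   missense     7 2.071024e-08
#> 4:   nonsense     3 8.875815e-09
#> 5:      indel     5 1.479303e-08
signif(inc$r_all, 2)           # 6.8e-08  mutations per base per genome
signif(inc$per_genome_mean, 2) # 0.82     mutations per genome

# hotspot locus: 8 mutant colonies of 192 screened, locus ~1e-4 of genome
enr <- locus_enrichment(8, 192, locus_len = 1207, genome_len = 12071326,
                        per_genome_rate = 0.82)
enr$observed_incidence  # 0.0417 (~4.2% of adapted colonies)
enr$expected            # 0.0157 expected under uniform mutagenesis
enr$p_value             # 9.2e-20: far more hotspot mutations than uniform
                        # mutagenesis at the genome-wide rate can explain

# emergence timing from the within-colony mutant fraction
emergence_generation(0.25)
#> generation 2, detectable_by_consensus TRUE
```

The contrast the numbers draw: the genome-wide mutation load of adapted
strains is unremarkable (0.82 mutations per genome; 6.8×10⁻⁸ per base),
yet the hotspot locus is mutated in ~4% of independently adapted colonies —
orders of magnitude above the uniform expectation — and the allele
fractions show these mutations arose within the first divisions after
growth resumed, i.e. after exposure to the challenge.

Simulate the whole design and run every stage:

```r
run_pipeline(list(out_dir = "demo", seed = 1))      # summary.json + VCF + TSVs
```

Command line (`inst/cli/adaptmut`):

```sh
adaptmut simulate-experiment --model induced --lineages 56 --seed 1 --out lineages.tsv
adaptmut run-all --out demo --seed 1
```

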