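Package: adaptmut
Title: Mutation Analysis for Yeast Lineages Adapting to a Regulatory Challenge
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse induced mutations in haploid yeast lineages
    adapting to an unforeseen regulatory challenge. Implements
    ancestor-versus-adapted variant calling from per-position nucleotide
    count tables, coverage-based whole-chromosome duplication detection,
    per-base mutation incidence and locus-enrichment statistics, inference
    of mutation emergence timing from within-colony allele fractions, and
    three-phase segmentation of colony growth curves. A synthetic-experiment
    simulator emulates the 96-well lineage-separation design under
    pre-existing (Luria-Delbruck) and induced mutation models, and a
    synthetic-genomics module generates toy references, count tables and
    coverage tracks with planted mutations, so the full pipeline can be
    exercised without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics,
    withr
Config/testthat/edition: 3
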