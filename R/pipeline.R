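# End-to-end pipeline and command-line entry point. The demo pipeline
# simulates an experiment + genomes, then runs QC, variant calling,
# duplication detection and the incidence/enrichment statistics, writing a
# machine-readable JSON summary. All randomness flows from one master seed,
# split per stage and per strain, so stage-level reruns reproduce
# pipeline-level results.

pipeline_defaults <- function() list(
  out_dir = "adaptmut_out",
  seed = 1L,
  # experiment
  n_lineages = 56L,
  mutation_model = "induced",
  # genomes
  n_strains = 8L,
  n_snp_per_strain = 2L,
  n_indel_per_strain = 1L,
  mean_depth = 30,
  error_rate = 0.005,
  duplicated_strains = 1L,
  # thresholds
  min_depth = 5L,
  min_alt_fraction_strain = 0.8,
  max_alt_fraction_ancestor = 0.05,
  mixed_min_fraction = 0.25,
  min_genome_covered = 0.8,
  # aneuploidy
  window_size = 5000L,
  n_windows = 200L,
  aneuploidy_band = c(1.75, 2.25),
  # stats
  genome_length = NULL,       # NULL = sum of simulated nuclear chromosomes
  locus_fraction = 1e-4,
  verbosity = 1L)

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected (fail-fast); threshold fields are checked via
#' [caller_thresholds()].
#'
#' @param config named list of overrides, or a path to a JSON file
#' @return validated full configuration list
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  # field validation (names surface in the error message)
  caller_thresholds(min_depth = cfg$min_depth,
                    min_alt_fraction_strain = cfg$min_alt_fraction_strain,
                    max_alt_fraction_ancestor = cfg$max_alt_fraction_ancestor,
                    mixed_min_fraction = cfg$mixed_min_fraction,
                    min_genome_covered = cfg$min_genome_covered)
  assert_count(cfg$n_lineages, "n_lineages")
  assert_count(cfg$n_strains, "n_strains")
  assert_prob(cfg$error_rate, "error_rate")
  assert_prob(cfg$locus_fraction, "locus_fraction")
  if (length(cfg$aneuploidy_band) != 2 ||
      cfg$aneuploidy_band[1] >= cfg$aneuploidy_band[2])
    stop("'aneuploidy_band' must be an increasing interval", call. = FALSE)
  cfg
}

#' Run the full demo pipeline
#'
#' Simulate -> QC -> variant calling -> aneuploidy -> statistics -> report.
#' Writes lineages.tsv, calls.vcf (+ .tsv mirror), qc.tsv, duplications.tsv
#' and summary.json under `config$out_dir`. Idempotent for a fixed seed.
#'
#' @param config list of overrides or JSON path; see [pipeline_config()]
#' @return (invisibly) the summary list
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  thr <- caller_thresholds(cfg$min_depth, cfg$min_alt_fraction_strain,
                           cfg$max_alt_fraction_ancestor,
                           cfg$mixed_min_fraction, cfg$min_genome_covered)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  quiet <- cfg$verbosity < 1

  # stage 1: lineage-separation experiment ----------------------------------
  params <- experiment_params(n_lineages = cfg$n_lineages,
                              mutation_model = cfg$mutation_model,
                              locus_fraction = cfg$locus_fraction,
                              seed = split_seed(cfg$seed, 1L))
  lineages <- simulate_lineage(params)
  write_lineage_table(lineages, file.path(cfg$out_dir, "lineages.tsv"))
  if (!quiet) am_log("sim_experiment", "%d colonies in %d lineages",
                     nrow(lineages), cfg$n_lineages)

  # stage 2: synthetic genomes ----------------------------------------------
  ref <- make_reference(seed = split_seed(cfg$seed, 2L))
  strains <- sprintf("s%02d", seq_len(cfg$n_strains))
  planted <- plant_mutations(ref, strains, n_snp = cfg$n_snp_per_strain,
                             n_indel = cfg$n_indel_per_strain,
                             seed = split_seed(cfg$seed, 3L))
  nuc <- setdiff(names(ref$chromosomes), ref$mito_chrom)
  dup <- if (cfg$duplicated_strains > 0)
    data.frame(strain_id = strains[seq_len(cfg$duplicated_strains)],
               chrom = rep_len(nuc[2], cfg$duplicated_strains))
  else NULL
  sim <- simulate_counts(ref, planted, strain_ids = c("ancestor", strains),
                         mean_depth = cfg$mean_depth,
                         error_rate = cfg$error_rate,
                         duplicated = dup, seed = split_seed(cfg$seed, 4L))

  # stage 3: coverage QC -----------------------------------------------------
  qc <- lapply(strains, function(s)
    strain_qc(sim$coverage[[s]], thr, mito_chrom = ref$mito_chrom))
  qc_tab <- data.table::data.table(
    strain_id = strains,
    fraction_covered = vapply(qc, `[[`, numeric(1),
                              "fraction_covered_ge_min_depth"),
    included = vapply(qc, `[[`, logical(1), "included"))
  data.table::fwrite(qc_tab, file.path(cfg$out_dir, "qc.tsv"), sep = "\t")
  included <- qc_tab$strain_id[qc_tab$included]
  if (!length(included)) stop("[qc] no strain passed coverage QC",
                              call. = FALSE)

  # stage 4: variant calling -------------------------------------------------
  anc <- sim$counts[["ancestor"]]
  nuc_only <- function(x) x[x$chrom %in% nuc, ]
  calls <- data.table::rbindlist(lapply(included, function(s) {
    sc <- nuc_only(sim$counts[[s]])
    rbind(call_snps(nuc_only(anc), sc, thr, verbose = !quiet),
          call_indels(nuc_only(anc), sc, ref, thr, verbose = !quiet))
  }))
  calls <- classify_mutations(calls, ref)
  write_vcf(calls, file.path(cfg$out_dir, "calls.vcf"), tsv_mirror = TRUE)

  # stage 5: aneuploidy ------------------------------------------------------
  dups <- data.table::rbindlist(lapply(included, function(s) {
    w <- sample_windows(nuc_only(sim$coverage[[s]]),
                        window_size = cfg$window_size,
                        n_windows = cfg$n_windows,
                        seed = split_seed(cfg$seed, 5L))
    call_duplications(w, band = cfg$aneuploidy_band)
  }))
  data.table::fwrite(dups, file.path(cfg$out_dir, "duplications.tsv"),
                     sep = "\t")

  # stage 6: statistics ------------------------------------------------------
  G <- if (is.null(cfg$genome_length))
    sum(Biostrings::width(ref$chromosomes[nuc])) else cfg$genome_length
  inc <- incidence_table(calls, n_strains = length(included),
                         genome_length = G)
  dist <- per_strain_distribution(calls, included)
  n_col <- nrow(lineages)
  k_mut <- length(unique(lineages$colony_id[!is.na(lineages$locus_id)]))
  enr <- locus_enrichment(observed_k = k_mut, n_colonies = max(n_col, 1),
                          locus_len = round(cfg$locus_fraction * G),
                          genome_len = G,
                          per_genome_rate = max(inc$per_genome_mean, 1e-12))

  summary <- list(
    seed = cfg$seed,
    n_strains_sequenced = length(strains),
    n_strains_included = length(included),
    genome_length = G,
    incidence = list(
      by_class = as.list(stats::setNames(inc$by_class$incidence,
                                         inc$by_class$class)),
      counts = as.list(stats::setNames(inc$by_class$count,
                                       inc$by_class$class)),
      total_count = inc$total_count,
      r_all = inc$r_all,
      per_genome_mean = inc$per_genome_mean),
    per_strain_histogram = as.list(dist$histogram),
    duplications = list(called = dups$chrom[dups$duplicated],
                        strains = dups$strain_id[dups$duplicated]),
    enrichment = list(observed_k = enr$observed_k,
                      n_colonies = enr$n_colonies,
                      observed_incidence = enr$observed_incidence,
                      expected = enr$expected,
                      p_value = enr$p_value))
  write_summary(summary, file.path(cfg$out_dir, "summary.json"))
  invisible(summary)
}

# ---------------------------------------------------------------------------
# command-line interface

parse_cli_args <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

num <- function(x, default = NULL) {
  if (is.null(x)) return(default)
  as.numeric(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate-experiment`, `simulate-genomes`, `call-variants`,
#' `call-duplications`, `mutation-stats` (`incidence` | `enrichment`),
#' `segment-growth`, `run-all`. Every subcommand accepts `--seed` and
#' `--out`; `run-all` accepts `--config` (JSON). Returns the exit status
#' (nonzero on contract violations); the installed script
#' `inst/cli/adaptmut` forwards `commandArgs(TRUE)` here.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status, invisibly
#' @export
adaptmut_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: adaptmut <subcommand> [--options]",
                            call. = FALSE)
    cmd <- args[1]
    rest <- args[-1]
    sub <- NULL
    if (length(rest) && !startsWith(rest[1], "--")) {   # sub-subcommand
      sub <- rest[1]; rest <- rest[-1]
    }
    opt <- parse_cli_args(rest)
    seed <- as.integer(num(opt$seed, 1))
    switch(cmd,
      "simulate-experiment" = {
        params <- experiment_params(
          n_lineages = as.integer(num(opt$lineages, 56)),
          mutation_model = if (is.null(opt$model)) "induced" else opt$model,
          seed = seed)
        tab <- simulate_lineage(params)
        write_lineage_table(tab, opt$out %||% "lineages.tsv")
      },
      "simulate-genomes" = {
        ref <- make_reference(seed = seed)
        out_dir <- opt$out %||% "."
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        strains <- sprintf("s%02d", seq_len(as.integer(num(opt$strains, 2))))
        planted <- plant_mutations(ref, strains, seed = split_seed(seed, 1))
        sim <- simulate_counts(ref, planted,
                               strain_ids = c("ancestor", strains),
                               seed = split_seed(seed, 2))
        write_reference(ref, file.path(out_dir, "ref.fa"),
                        file.path(out_dir, "genes.tsv"))
        for (s in names(sim$counts))
          write_count_table(sim$counts[[s]],
                            file.path(out_dir, paste0(s, ".counts.tsv")))
        data.table::fwrite(planted, file.path(out_dir, "planted.tsv"),
                           sep = "\t", na = "")
      },
      "call-variants" = {
        anc <- read_count_table(opt$ancestor)
        st <- read_count_table(opt$strain)
        ref <- read_reference(opt$ref, opt$genes)
        calls <- rbind(call_snps(anc, st), call_indels(anc, st, ref))
        calls <- classify_mutations(calls, ref)
        write_vcf(calls, opt$out %||% "calls.vcf", tsv_mirror = TRUE)
      },
      "call-duplications" = {
        track <- read_coverage(opt$coverage)
        w <- sample_windows(track, seed = seed)
        dups <- call_duplications(w)
        data.table::fwrite(dups, opt$out %||% "duplications.tsv", sep = "\t")
      },
      "mutation-stats" = {
        if (is.null(sub))
          stop("mutation-stats needs 'incidence' or 'enrichment'",
               call. = FALSE)
        if (sub == "incidence") {
          calls <- data.table::fread(opt$calls, sep = "\t",
                                     na.strings = c("", "NA"))
          inc <- incidence_table(calls,
                                 n_strains = as.integer(num(opt$strains)),
                                 genome_length = num(opt$genome_length,
                                                     12071326))
          write_summary(list(by_class = as.list(
            stats::setNames(inc$by_class$incidence, inc$by_class$class)),
            r_all = inc$r_all, per_genome_mean = inc$per_genome_mean),
            opt$out %||% "incidence.json")
        } else if (sub == "enrichment") {
          enr <- locus_enrichment(
            observed_k = as.integer(num(opt$observed)),
            n_colonies = as.integer(num(opt$colonies)),
            locus_len = num(opt$locus_len),
            genome_len = num(opt$genome_len, 12071326),
            per_genome_rate = num(opt$rate, 0.82))
          write_summary(enr[c("observed_k", "n_colonies",
                              "observed_incidence", "expected", "p_value")],
                        opt$out %||% "enrichment.json")
        } else stop("unknown mutation-stats subcommand: ", sub, call. = FALSE)
      },
      "segment-growth" = {
        tab <- data.table::fread(opt$series, sep = "\t")
        seg <- segment_phases(list(t = tab[[1]], area = tab[[2]]))
        write_summary(list(changepoints = as.list(seg$changepoints),
                           slopes = as.list(seg$slopes), sse = seg$sse,
                           valid_three_phase = seg$valid_three_phase),
                      opt$out %||% "segmentation.json")
      },
      "run-all" = {
        cfg <- if (!is.null(opt$config)) opt$config else list()
        if (is.list(cfg)) {
          if (!is.null(opt$out)) cfg$out_dir <- opt$out
          if (!is.null(opt$seed)) cfg$seed <- seed
        }
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
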