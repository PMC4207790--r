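# Ancestor-vs-adapted variant calling from per-position nucleotide count
# tables. The ancestor consensus base defines the local reference; an adapted
# strain is called at a position when its alternative base is near-fixed
# while the ancestor shows (almost) none of it. Haploid background: mixed
# base signals represent colony heterogeneity, not heterozygosity.

#' Variant-caller thresholds
#'
#' @param min_depth minimum read depth required in both ancestor and strain
#'   (default 5, the study's per-base coverage floor)
#' @param min_alt_fraction_strain minimum alternative-allele fraction in the
#'   adapted strain (default 0.8; clonal haploid colonies are near-fixed)
#' @param max_alt_fraction_ancestor maximum fraction of the same allele
#'   tolerated in the ancestor (default 0.05)
#' @param mixed_min_fraction minor-allele fraction at which a site counts as
#'   mixed, Sanger-style (default 0.25, i.e. a rare allele of 25% or more)
#' @param min_genome_covered fraction of the nuclear genome that must reach
#'   `min_depth` for a strain to pass QC (default 0.8)
#' @return list of class `caller_thresholds`
#' @export
caller_thresholds <- function(min_depth = 5L,
                              min_alt_fraction_strain = 0.8,
                              max_alt_fraction_ancestor = 0.05,
                              mixed_min_fraction = 0.25,
                              min_genome_covered = 0.8) {
  assert_count(min_depth, "min_depth", min = 0)
  assert_prob(min_alt_fraction_strain, "min_alt_fraction_strain")
  assert_prob(max_alt_fraction_ancestor, "max_alt_fraction_ancestor")
  assert_prob(mixed_min_fraction, "mixed_min_fraction")
  assert_prob(min_genome_covered, "min_genome_covered")
  if (!(max_alt_fraction_ancestor < min_alt_fraction_strain))
    stop("max_alt_fraction_ancestor must be < min_alt_fraction_strain",
         call. = FALSE)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_fraction_strain = min_alt_fraction_strain,
                 max_alt_fraction_ancestor = max_alt_fraction_ancestor,
                 mixed_min_fraction = mixed_min_fraction,
                 min_genome_covered = min_genome_covered),
            class = "caller_thresholds")
}

#' Strain coverage QC
#'
#' A strain is retained when at least `min_genome_covered` of its nuclear
#' positions have depth >= `min_depth` (five reads per base in 80% or more of
#' the nuclear genome, by default). Mitochondrial positions are excluded.
#'
#' @param track a `coverage_track` (strain_id, chrom, pos, depth)
#' @param thresholds a [caller_thresholds()] object
#' @param mito_chrom mitochondrial chromosome name to exclude, or NA
#' @return list of class `strain_qc_report`: strain_id,
#'   `fraction_covered_ge_min_depth`, `included`
#' @export
strain_qc <- function(track, thresholds = caller_thresholds(),
                      mito_chrom = NA_character_) {
  nuc <- if (is.na(mito_chrom)) track else track[track$chrom != mito_chrom, ]
  if (nrow(nuc) == 0)
    stop("coverage track has no nuclear positions", call. = FALSE)
  frac <- mean(nuc$depth >= thresholds$min_depth)
  structure(list(strain_id = nuc$strain_id[1],
                 fraction_covered_ge_min_depth = frac,
                 included = frac >= thresholds$min_genome_covered),
            class = "strain_qc_report")
}

# empty MutationCall table (shared schema)
empty_calls <- function() {
  data.table::data.table(
    strain_id = character(0), chrom = character(0), pos = integer(0),
    ref_allele = character(0), alt_allele = character(0),
    type = character(0), functional_class = character(0),
    alt_fraction = numeric(0), indel_len = integer(0),
    protein_pos = integer(0), aa_ref = character(0), aa_alt = character(0),
    gene_id = character(0), needs_review = logical(0))
}

#' Call adapted-strain-specific SNPs against the ancestor
#'
#' At each position covered in both tables, the ancestor consensus (majority)
#' base is taken as reference. A SNP is emitted when the strain's best
#' non-reference base reaches `min_alt_fraction_strain` of its depth, the
#' ancestor carries at most `max_alt_fraction_ancestor` of that base, and
#' both depths reach `min_depth`. Sites below `min_depth` are no-calls (not
#' reference) and are counted in the log; positions present in the strain but
#' absent from the ancestor are skipped and logged, never called.
#'
#' @param ancestor,strain nucleotide count tables (strain_id, chrom, pos,
#'   A, C, G, T, ins, del, depth)
#' @param thresholds a [caller_thresholds()] object
#' @param verbose emit per-filter counts to stderr
#' @return data.table of mutation calls sorted by (chrom, pos); columns as
#'   [empty_calls()] with `type = "snp"` and `functional_class = NA` (fill
#'   with [classify_mutations()])
#' @export
call_snps <- function(ancestor, strain, thresholds = caller_thresholds(),
                      verbose = TRUE) {
  bases <- c("A", "C", "G", "T")
  m <- merge(ancestor[, c("chrom", "pos", "A", "C", "G", "T", "depth")],
             strain[, c("strain_id", "chrom", "pos", "A", "C", "G", "T",
                        "depth")],
             by = c("chrom", "pos"), suffixes = c(".anc", ".str"))
  n_absent <- nrow(strain) - nrow(m)
  anc_mat <- as.matrix(m[, paste0(bases, ".anc"), with = FALSE])
  str_mat <- as.matrix(m[, paste0(bases, ".str"), with = FALSE])
  ref_idx <- max.col(anc_mat, ties.method = "first")
  tmp <- str_mat
  tmp[cbind(seq_len(nrow(tmp)), ref_idx)] <- -1L
  alt_idx <- max.col(tmp, ties.method = "first")
  rows <- seq_len(nrow(m))
  str_alt_frac <- str_mat[cbind(rows, alt_idx)] / pmax(m$depth.str, 1L)
  anc_alt_frac <- anc_mat[cbind(rows, alt_idx)] / pmax(m$depth.anc, 1L)
  deep <- m$depth.anc >= thresholds$min_depth &
    m$depth.str >= thresholds$min_depth
  hit <- deep & str_alt_frac >= thresholds$min_alt_fraction_strain &
    anc_alt_frac <= thresholds$max_alt_fraction_ancestor
  if (verbose)
    am_log("call_snps",
           "%d sites, %d absent-in-ancestor skipped, %d no-call (depth < %d), %d SNPs",
           nrow(m), n_absent, sum(!deep), thresholds$min_depth, sum(hit))
  if (!any(hit)) return(empty_calls())
  out <- data.table::data.table(
    strain_id = m$strain_id[hit], chrom = m$chrom[hit], pos = m$pos[hit],
    ref_allele = bases[ref_idx[hit]], alt_allele = bases[alt_idx[hit]],
    type = "snp", functional_class = NA_character_,
    alt_fraction = str_alt_frac[hit], indel_len = NA_integer_,
    protein_pos = NA_integer_, aa_ref = NA_character_,
    aa_alt = NA_character_, gene_id = NA_character_, needs_review = FALSE)
  data.table::setorderv(out, c("chrom", "pos"))
  out[]
}

#' Low-complexity context test for indel filtering
#'
#' TRUE when the position lies in a homopolymer run of at least
#' `min_homopolymer` identical bases, or inside a perfect 2- or 3-mer tandem
#' repeat spanning at least `min_tandem_span` bp. Both the anchor base and
#' its right neighbour are tested (insertion evidence is anchored left).
#'
#' @param chrom_seq character vector of single bases for the chromosome
#' @param pos 1-based position
#' @param min_homopolymer,min_tandem_span rule parameters (defaults 6 and 12)
#' @return logical
#' @export
is_low_complexity <- function(chrom_seq, pos, min_homopolymer = 6L,
                              min_tandem_span = 12L) {
  L <- length(chrom_seq)
  run_len <- function(p) {
    b <- chrom_seq[p]
    l <- p; while (l > 1 && chrom_seq[l - 1] == b) l <- l - 1
    r <- p; while (r < L && chrom_seq[r + 1] == b) r <- r + 1
    r - l + 1
  }
  if (run_len(pos) >= min_homopolymer) return(TRUE)
  if (pos < L && run_len(pos + 1) >= min_homopolymer) return(TRUE)
  for (p in 2:3) {
    # maximal interval around pos where s[i] == s[i + p]
    l <- pos; r <- pos
    while (l > 1 && l - 1 + p <= L && chrom_seq[l - 1] == chrom_seq[l - 1 + p])
      l <- l - 1
    while (r + p <= L && chrom_seq[r] == chrom_seq[r + p])
      r <- r + 1
    span <- (r + p - 1) - l + 1
    if (span >= min_tandem_span && r > l) return(TRUE)
  }
  FALSE
}

#' Call adapted-strain-specific indels against the ancestor
#'
#' Insertion/deletion evidence counts are compared like SNP fractions: a
#' candidate needs strain evidence fraction >= `min_alt_fraction_strain`,
#' ancestor fraction <= `max_alt_fraction_ancestor`, and depth >= `min_depth`
#' in both. Candidates in low-complexity sequence (homopolymer or short
#' tandem repeat context, see [is_low_complexity()]) are dropped and logged
#' -- the automated stand-in for manual alignment inspection.
#'
#' @inheritParams call_snps
#' @param ref a `synthetic_reference` providing sequence context
#' @return data.table of indel calls (type "ins"/"del", indel_len 1)
#' @export
call_indels <- function(ancestor, strain, ref,
                        thresholds = caller_thresholds(), verbose = TRUE) {
  m <- merge(ancestor[, c("chrom", "pos", "ins", "del", "depth")],
             strain[, c("strain_id", "chrom", "pos", "ins", "del", "depth")],
             by = c("chrom", "pos"), suffixes = c(".anc", ".str"))
  deep <- m$depth.anc >= thresholds$min_depth &
    m$depth.str >= thresholds$min_depth
  out <- list()
  for (ev in c("ins", "del")) {
    sf <- m[[paste0(ev, ".str")]] / pmax(m$depth.str, 1L)
    af <- m[[paste0(ev, ".anc")]] / pmax(m$depth.anc, 1L)
    hit <- which(deep & sf >= thresholds$min_alt_fraction_strain &
                   af <= thresholds$max_alt_fraction_ancestor)
    if (!length(hit)) next
    out[[ev]] <- data.table::data.table(
      strain_id = m$strain_id[hit], chrom = m$chrom[hit], pos = m$pos[hit],
      type = ev, alt_fraction = sf[hit])
  }
  cand <- data.table::rbindlist(out)
  if (nrow(cand) == 0) {
    if (verbose) am_log("call_indels", "0 candidates")
    return(empty_calls())
  }
  seqs <- lapply(names(ref$chromosomes), function(ch)
    strsplit(as.character(ref$chromosomes[[ch]]), "")[[1]])
  names(seqs) <- names(ref$chromosomes)
  lc <- vapply(seq_len(nrow(cand)), function(k)
    is_low_complexity(seqs[[cand$chrom[k]]], cand$pos[k]), logical(1))
  if (verbose)
    am_log("call_indels", "%d candidates, %d dropped as low-complexity",
           nrow(cand), sum(lc))
  cand <- cand[!lc, ]
  if (nrow(cand) == 0) return(empty_calls())
  out <- data.table::data.table(
    strain_id = cand$strain_id, chrom = cand$chrom, pos = cand$pos,
    ref_allele = vapply(seq_len(nrow(cand)), function(k)
      seqs[[cand$chrom[k]]][cand$pos[k]], character(1)),
    alt_allele = ifelse(cand$type == "ins", "<INS>", "<DEL>"),
    type = cand$type, functional_class = NA_character_,
    alt_fraction = cand$alt_fraction, indel_len = 1L,
    protein_pos = NA_integer_, aa_ref = NA_character_,
    aa_alt = NA_character_, gene_id = NA_character_, needs_review = FALSE)
  data.table::setorderv(out, c("chrom", "pos"))
  out[]
}

# complement of DNA bases in character representation
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' Classify mutation calls functionally
#'
#' SNPs outside genes are intergenic; inside a gene the affected codon is
#' translated before and after (strand-aware, standard genetic code) giving
#' synonymous, missense, or nonsense. Indels inside a gene are
#' `inframe_indel` when their length is divisible by 3, else `frameshift`.
#' Protein position is `ceil(cds_offset / 3)` with `cds_offset` the 1-based
#' offset from the first base of the start codon. A deletion overlapping a
#' gene boundary is refused (`needs_review = TRUE`, class `NA`), mirroring a
#' manual-inspection queue.
#'
#' @param calls a mutation-call table from [call_snps()] / [call_indels()]
#' @param ref a `synthetic_reference`
#' @param gene_model gene table (gene_id, chrom, start, end, strand);
#'   defaults to `ref$gene_model`
#' @return the calls table with `functional_class`, `protein_pos`, `aa_ref`,
#'   `aa_alt`, `gene_id` filled
#' @export
classify_mutations <- function(calls, ref, gene_model = ref$gene_model) {
  if (nrow(calls) == 0) return(calls)
  calls <- data.table::copy(calls)
  gc_tab <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(calls))) {
    ch <- calls$chrom[k]; pos <- calls$pos[k]
    g <- gene_model[gene_model$chrom == ch & gene_model$start <= pos &
                      gene_model$end >= pos, ]
    if (nrow(g) == 0) {
      calls$functional_class[k] <-
        if (calls$type[k] == "snp") "intergenic" else "intergenic"
      next
    }
    g <- g[1, ]
    calls$gene_id[k] <- g$gene_id
    if (calls$type[k] != "snp") {
      len <- calls$indel_len[k]
      if (calls$type[k] == "del" && pos + len - 1L > g$end) {
        calls$needs_review[k] <- TRUE          # spans the gene boundary
        next
      }
      calls$functional_class[k] <-
        if (len %% 3L == 0L) "inframe_indel" else "frameshift"
      cds_off <- if (g$strand == "+") pos - g$start + 1L else g$end - pos + 1L
      calls$protein_pos[k] <- as.integer(ceiling(cds_off / 3))
      next
    }
    cds_off <- if (g$strand == "+") pos - g$start + 1L else g$end - pos + 1L
    codon_idx <- as.integer(ceiling(cds_off / 3))
    within <- cds_off - 3L * (codon_idx - 1L)
    cds <- as.character(Biostrings::subseq(ref$chromosomes[[ch]],
                                           g$start, g$end))
    if (g$strand == "-")
      cds <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
    alt_cds <- if (g$strand == "+") calls$alt_allele[k]
               else dna_complement(calls$alt_allele[k])
    new_codon <- codon
    substr(new_codon, within, within) <- alt_cds
    aa_ref <- unname(gc_tab[codon]); aa_alt <- unname(gc_tab[new_codon])
    calls$protein_pos[k] <- codon_idx
    calls$aa_ref[k] <- aa_ref
    calls$aa_alt[k] <- aa_alt
    calls$functional_class[k] <-
      if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"
  }
  calls[]
}

#' Detect a heterogeneous (mixed) colony from minor-allele fractions
#'
#' A site is mixed when its minor-allele fraction reaches
#' `mixed_min_fraction` (inclusive: a rare allele of 25% or more by default,
#' the Sanger-trace detectability rule); a colony with at least one mixed
#' site is flagged heterogeneous.
#'
#' @param site_fractions data.frame with columns `pos` and `minor_fraction`
#' @param thresholds a [caller_thresholds()] object
#' @return list of class `mixed_colony_report`: `heterogeneous`,
#'   `mixed_sites` (subset of input rows)
#' @export
detect_mixed_colony <- function(site_fractions,
                                thresholds = caller_thresholds()) {
  if (any(site_fractions$minor_fraction < 0 |
            site_fractions$minor_fraction > 1))
    stop("minor-allele fractions must lie in [0, 1]", call. = FALSE)
  mixed <- site_fractions[site_fractions$minor_fraction >=
                            thresholds$mixed_min_fraction, , drop = FALSE]
  structure(list(heterogeneous = nrow(mixed) > 0, mixed_sites = mixed),
            class = "mixed_colony_report")
}
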