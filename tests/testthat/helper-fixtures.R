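# Shared fixtures and independent oracles, all built in code.

# small fast reference: 3 nuclear chromosomes + mito, short genes
tiny_reference <- function(seed = 42, mito = TRUE) {
  make_reference(n_chrom = 3L, lengths = c(6000L, 5000L, 4500L),
                 genes_per_chrom = 4L, gene_length_range = c(60L, 150L),
                 mito = mito, seed = seed)
}

# hand-built single-gene reference for codon arithmetic tests.
# The gene body is a prescribed CDS embedded with flanks; coordinates are
# chosen so specific codons sit at known protein positions.
codon_reference <- function(cds, flank = 30L, strand = "+", seed = 7) {
  stopifnot(nchar(cds) %% 3 == 0)
  set.seed(seed)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  left <- pad(flank); right <- pad(flank)
  chrom_seq <- if (strand == "+") paste0(left, cds, right)
  else paste0(left, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds))), right)
  structure(list(
    chromosomes = Biostrings::DNAStringSet(c(chrT = chrom_seq)),
    gene_model = data.table::data.table(
      gene_id = "GT.01", chrom = "chrT",
      start = flank + 1L, end = flank + nchar(cds),
      strand = strand),
    mito_chrom = NA_character_
  ), class = "synthetic_reference")
}

# a CDS of n_codons "CTG" (Leu) codons with substitutions at given codon
# indices: list(index = "NNN")
make_cds <- function(n_codons, replace = list()) {
  codons <- rep("CTG", n_codons)
  for (i in names(replace)) codons[as.integer(i)] <- replace[[i]]
  paste(codons, collapse = "")
}

# independent classification oracle: rebuild the full mutant CDS, translate
# both proteins with Biostrings::translate, and compare end to end
oracle_classify_snp <- function(ref, gene, pos, alt) {
  chrom <- as.character(ref$chromosomes[[gene$chrom]])
  mutant <- chrom
  substr(mutant, pos, pos) <- alt
  cds_of <- function(s) {
    cds <- substr(s, gene$start, gene$end)
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    cds
  }
  aa <- function(s) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_of(s)), no.init.codon = TRUE)), "")[[1]]
  p0 <- aa(chrom); p1 <- aa(mutant)
  d <- which(p0 != p1)
  if (!length(d)) return("synonymous")
  if (p1[d[1]] == "*") "nonsense" else "missense"
}

# one-row mutation-call table with the caller's schema (type snp by default)
empty_nucleotide_call <- function(strain, chrom, pos, alt) {
  data.table::data.table(
    strain_id = strain, chrom = chrom, pos = as.integer(pos),
    ref_allele = NA_character_, alt_allele = alt, type = "snp",
    functional_class = NA_character_, alt_fraction = 1,
    indel_len = NA_integer_, protein_pos = NA_integer_,
    aa_ref = NA_character_, aa_alt = NA_character_,
    gene_id = NA_character_, needs_review = FALSE)
}

# minor-allele fraction per site from a count-table row subset
minor_fraction <- function(counts) {
  m <- as.matrix(counts[, c("A", "C", "G", "T")])
  1 - apply(m, 1, max) / pmax(rowSums(m), 1)
}

# standard planted-mutation fixture used by calling tests and acceptance:
# one adapted strain with planted SNPs/indels on a clean background
planted_fixture <- function(ref, n_snp, n_indel = 0L, mean_depth = 30,
                            error_rate = 0.005, seed = 99) {
  pl <- plant_mutations(ref, "s1", n_snp = n_snp, n_indel = n_indel,
                        coding_only = FALSE, seed = seed)
  sim <- simulate_counts(ref, pl, strain_ids = c("ancestor", "s1"),
                         mean_depth = mean_depth, error_rate = error_rate,
                         seed = seed + 1L)
  list(planted = pl, sim = sim)
}
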