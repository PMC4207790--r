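# Readers/writers for the package's plain-text dialects. All coordinates are
# 1-based inclusive; all tables are TSV with mandatory headers. VCF 4.2 is
# used for variant export only.

#' Write / read a nucleotide count table
#'
#' TSV columns: strain, chrom, pos, A, C, G, T, ins, del (1-based positions).
#' `depth` is recomputed on read as A + C + G + T.
#'
#' @param tab count table
#' @param path file path
#' @return `read_count_table` returns a `count_table` data.table
#' @export
write_count_table <- function(tab, path) {
  out <- data.table::data.table(
    strain = tab$strain_id, chrom = tab$chrom, pos = tab$pos,
    A = tab$A, C = tab$C, G = tab$G, T = tab$T,
    ins = tab$ins, del = tab$del)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("strain", "chrom", "pos", "A", "C", "G", "T", "ins", "del")
  if (!all(need %in% names(tab)))
    stop("count table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(tab$pos < 1 | tab$A < 0 | tab$C < 0 | tab$G < 0 | tab$T < 0 |
                 tab$ins < 0 | tab$del < 0)
  if (length(bad))
    stop("malformed count-table rows (1-based data lines): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  out <- data.table::data.table(
    strain_id = tab$strain, chrom = tab$chrom, pos = as.integer(tab$pos),
    A = as.integer(tab$A), C = as.integer(tab$C), G = as.integer(tab$G),
    T = as.integer(tab$T), ins = as.integer(tab$ins),
    del = as.integer(tab$del))
  out$depth <- out$A + out$C + out$G + out$T
  data.table::setattr(out, "class", c("count_table", class(out)))
  out[]
}

#' Write / read a coverage track (TSV: strain, chrom, pos, depth; 1-based)
#' @param track coverage track
#' @param path file path
#' @export
write_coverage <- function(track, path) {
  out <- data.table::data.table(strain = track$strain_id, chrom = track$chrom,
                                pos = track$pos, depth = track$depth)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("strain", "chrom", "pos", "depth")
  if (!all(need %in% names(tab)))
    stop("coverage track must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- data.table::data.table(strain_id = tab$strain, chrom = tab$chrom,
                                pos = as.integer(tab$pos),
                                depth = as.numeric(tab$depth))
  data.table::setattr(out, "class", c("coverage_track", class(out)))
  out[]
}

#' Write / read a gene model (TSV: gene_id, chrom, start, end, strand)
#' @param gene_model gene table
#' @param path file path
#' @export
write_gene_model <- function(gene_model, path) {
  data.table::fwrite(gene_model[, c("gene_id", "chrom", "start", "end",
                                    "strand")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene model must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(tab$start > tab$end | tab$start < 1 |
                 !tab$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed gene-model rows (1-based data lines): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab[]
}

#' Write / read a lineage table
#'
#' TSV: lineage_id, colony_id, adapted, locus_id, emergence_generation,
#' mutant_fraction; one row per colony-mutation pair, mutation fields empty
#' for mutation-free colonies.
#'
#' @param tab a `lineage_table`
#' @param path file path
#' @param n_lineages on read: total lineages (default: max id in file)
#' @export
write_lineage_table <- function(tab, path) {
  data.table::fwrite(tab[, c("lineage_id", "colony_id", "adapted", "locus_id",
                             "emergence_generation", "mutant_fraction")],
                     path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_lineage_table
#' @export
read_lineage_table <- function(path, n_lineages = NULL) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"))
  tab$lineage_id <- as.integer(tab$lineage_id)
  tab$emergence_generation <- as.integer(tab$emergence_generation)
  tab$mutant_fraction[is.na(tab$mutant_fraction)] <- 0
  if (is.null(n_lineages)) n_lineages <- max(tab$lineage_id)
  data.table::setattr(tab, "n_lineages", as.integer(n_lineages))
  data.table::setattr(tab, "class", c("lineage_table", class(tab)))
  tab[]
}

#' Write reference FASTA and gene model
#' @param ref a `synthetic_reference`
#' @param fasta_path,genes_path output paths (NULL to skip either)
#' @export
write_reference <- function(ref, fasta_path = NULL, genes_path = NULL) {
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(ref$chromosomes, fasta_path)
  if (!is.null(genes_path))
    write_gene_model(ref$gene_model, genes_path)
  invisible(ref)
}

#' Read a reference FASTA (+ optional gene model) into a synthetic_reference
#' @param fasta_path FASTA file
#' @param genes_path gene model TSV or NULL
#' @param mito_chrom mitochondrial chromosome name or NA
#' @export
read_reference <- function(fasta_path, genes_path = NULL,
                           mito_chrom = NA_character_) {
  chroms <- Biostrings::readDNAStringSet(fasta_path)
  names(chroms) <- sub("\\s.*$", "", names(chroms))
  gm <- if (is.null(genes_path)) data.table::data.table(
    gene_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0)) else read_gene_model(genes_path)
  structure(list(chromosomes = chroms, gene_model = gm,
                 mito_chrom = mito_chrom),
            class = "synthetic_reference")
}

#' Write mutation calls as VCF 4.2
#'
#' One row per call; CHROM/POS are 1-based; indels use symbolic ALT alleles
#' `<INS>`/`<DEL>`. INFO carries TYPE, CLASS, AF and STRAIN; haploid
#' genotypes are written as one GT column per strain (1 = carries the
#' variant). A TSV mirror with the same rows is written alongside when
#' `tsv_mirror = TRUE`.
#'
#' @param calls mutation-call table
#' @param path output VCF path
#' @param tsv_mirror also write `<path>.tsv`
#' @export
write_vcf <- function(calls, path, tsv_mirror = FALSE) {
  strains <- sort(unique(calls$strain_id))
  if (!length(strains)) strains <- "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=adaptmut",
           "##ALT=<ID=INS,Description=\"Insertion relative to the ancestor consensus\">",
           "##ALT=<ID=DEL,Description=\"Deletion relative to the ancestor consensus\">",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snp, ins or del\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction in the colony\">",
           "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Adapted strain carrying the variant\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strains),
                 collapse = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, ]
    alt <- ifelse(calls$type == "snp", calls$alt_allele, calls$alt_allele)
    info <- sprintf("TYPE=%s;CLASS=%s;AF=%.4g;STRAIN=%s",
                    calls$type,
                    ifelse(is.na(calls$functional_class), ".",
                           calls$functional_class),
                    calls$alt_fraction, calls$strain_id)
    gt <- vapply(seq_len(nrow(calls)), function(k)
      paste(ifelse(strains == calls$strain_id[k], "1", "."), collapse = "\t"),
      character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                    calls$chrom, calls$pos, calls$ref_allele, alt, info, gt)
  }
  writeLines(c(hdr, body), path)
  if (tsv_mirror)
    data.table::fwrite(calls, paste0(path, ".tsv"), sep = "\t", na = "")
  invisible(path)
}

#' Write a machine-readable summary (JSON)
#' @param results named list
#' @param path output path
#' @export
write_summary <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
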