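# Synthetic haploid genomes: a toy multi-chromosome reference with a
# non-overlapping gene model, planted SNPs/indels, and per-strain nucleotide
# count tables plus coverage tracks. No read-level simulation: counts are
# drawn directly (Poisson depth, uniform base-error model).

#' Generate a toy haploid reference genome with a gene model
#'
#' Chromosome sequences are uniform over A/C/G/T. Genes are packed
#' non-overlapping on alternating strands, with lengths divisible by 3 so
#' every gene is a complete CDS (start..end inclusive, 1-based). Optionally a
#' small mitochondrial chromosome (no genes) is appended; downstream analyses
#' exclude it.
#'
#' @param n_chrom number of nuclear chromosomes
#' @param lengths integer vector of chromosome lengths (bp), recycled to
#'   `n_chrom`
#' @param genes_per_chrom genes to pack on each nuclear chromosome
#' @param gene_length_range codon-count range for gene lengths (default
#'   100-500 codons, i.e. 300-1500 bp)
#' @param mito if TRUE, append a 6 kb `"chrM"` mitochondrial chromosome
#' @param seed RNG seed; the reference is byte-deterministic per seed
#' @return list of class `synthetic_reference`: `chromosomes` (a named
#'   [Biostrings::DNAStringSet]), `gene_model` (data.table: gene_id, chrom,
#'   start, end, strand), `mito_chrom` (name or NA)
#' @export
make_reference <- function(n_chrom = 3L,
                           lengths = c(50000L, 40000L, 30000L),
                           genes_per_chrom = 10L,
                           gene_length_range = c(100L, 500L),
                           mito = TRUE,
                           seed = 1L) {
  n_chrom <- assert_count(n_chrom, "n_chrom")
  lengths <- rep_len(as.integer(lengths), n_chrom)
  genes_per_chrom <- assert_count(genes_per_chrom, "genes_per_chrom", min = 0)
  max_gene_bp <- 3L * gene_length_range[2]
  if (any(lengths < 3L * max_gene_bp))
    stop("chromosome lengths must be at least 3x the longest gene",
         call. = FALSE)
  local_seed(seed, {
    chrom_names <- paste0("chr", as.roman(seq_len(n_chrom)))
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- chrom_names
    genes <- vector("list", n_chrom)
    for (i in seq_len(n_chrom)) {
      if (genes_per_chrom == 0L) next
      n_codons <- sample(gene_length_range[1]:gene_length_range[2],
                         genes_per_chrom, replace = TRUE)
      glen <- 3L * n_codons
      # even slotting: the chromosome is cut into genes_per_chrom slots and
      # each gene starts at a random offset within its slot
      slot <- lengths[i] %/% genes_per_chrom
      if (any(glen >= slot))
        stop("infeasible gene packing: gene longer than its slot", call. = FALSE)
      start <- (seq_len(genes_per_chrom) - 1L) * slot +
        vapply(slot - glen, function(room) sample.int(room, 1L), integer(1))
      genes[[i]] <- data.table::data.table(
        gene_id = sprintf("G%s.%02d", i, seq_len(genes_per_chrom)),
        chrom = chrom_names[i],
        start = start,
        end = start + glen - 1L,
        strand = rep_len(c("+", "-"), genes_per_chrom))
    }
    gene_model <- data.table::rbindlist(genes)
    mito_chrom <- NA_character_
    if (mito) {
      mito_chrom <- "chrM"
      seqs[[mito_chrom]] <- paste(
        sample(c("A", "C", "G", "T"), 6000L, replace = TRUE), collapse = "")
    }
    structure(list(
      chromosomes = Biostrings::DNAStringSet(seqs),
      gene_model = gene_model,
      mito_chrom = mito_chrom
    ), class = "synthetic_reference")
  })
}

#' Plant a random mutation set on a reference
#'
#' Draws `n_snp` SNPs and `n_indel` 1-bp indels for each strain at distinct
#' positions on nuclear chromosomes. `coding_only = TRUE` restricts positions
#' to gene bodies (useful for exercising functional classification).
#'
#' @param ref a `synthetic_reference`
#' @param strain_ids character vector of strain names
#' @param n_snp,n_indel mutations per strain
#' @param coding_only restrict to gene bodies
#' @param seed RNG seed
#' @return data.table of class `planted_mutations`: strain_id, chrom, pos,
#'   ref_allele, alt_allele, type ("snp", "ins", "del"), indel_len, fraction
#'   (within-colony mutant fraction; 1 = clonal)
#' @export
plant_mutations <- function(ref, strain_ids, n_snp = 3L, n_indel = 1L,
                            coding_only = FALSE, seed = 1L) {
  nuc <- setdiff(names(ref$chromosomes), ref$mito_chrom)
  local_seed(seed, {
    out <- lapply(seq_along(strain_ids), function(si) {
      n <- n_snp + n_indel
      if (n == 0) return(NULL)
      if (coding_only) {
        gm <- ref$gene_model
        idx <- sample.int(nrow(gm), n, replace = TRUE)
        chrom <- gm$chrom[idx]
        pos <- gm$start[idx] +
          vapply(gm$end[idx] - gm$start[idx] + 1L,
                 function(w) sample.int(w, 1L) - 1L, integer(1))
      } else {
        chrom <- sample(nuc, n, replace = TRUE,
                        prob = Biostrings::width(ref$chromosomes[nuc]))
        pos <- vapply(chrom, function(ch)
          sample.int(length(ref$chromosomes[[ch]]), 1L), integer(1))
      }
      refb <- vapply(seq_len(n), function(k)
        as.character(Biostrings::subseq(ref$chromosomes[[chrom[k]]],
                                        pos[k], pos[k])), character(1))
      type <- c(rep("snp", n_snp), sample(c("ins", "del"), n_indel,
                                          replace = TRUE))
      altb <- ifelse(type == "snp",
                     vapply(refb, function(b)
                       sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1)),
                     NA_character_)
      data.table::data.table(
        strain_id = strain_ids[si], chrom = chrom, pos = pos,
        ref_allele = refb, alt_allele = altb, type = type,
        indel_len = ifelse(type == "snp", NA_integer_, 1L),
        fraction = 1)
    })
    tab <- data.table::rbindlist(out)
    if (nrow(tab) == 0)
      tab <- data.table::data.table(
        strain_id = character(0), chrom = character(0), pos = integer(0),
        ref_allele = character(0), alt_allele = character(0),
        type = character(0), indel_len = integer(0), fraction = numeric(0))
    # distinct positions per strain (resample collisions away is overkill at
    # toy scale; just drop duplicates)
    tab <- unique(tab, by = c("strain_id", "chrom", "pos"))
    data.table::setattr(tab, "class",
                        c("planted_mutations", class(tab)))
    tab[]
  })
}

#' Simulate a per-position coverage track
#'
#' Depth is Poisson with mean `mean_depth`, doubled on chromosomes listed in
#' `duplicated_chroms` (haploid background, so a whole-chromosome duplication
#' doubles coverage).
#'
#' @param ref a `synthetic_reference`
#' @param strain_id strain name stored in the track
#' @param mean_depth expected reads per base
#' @param duplicated_chroms character vector of duplicated chromosome names
#' @param seed RNG seed
#' @return data.table of class `coverage_track`: strain_id, chrom, pos, depth
#' @export
simulate_coverage <- function(ref, strain_id = "s1", mean_depth = 30,
                              duplicated_chroms = character(0), seed = 1L) {
  assert_pos(mean_depth, "mean_depth")
  bad <- setdiff(duplicated_chroms, names(ref$chromosomes))
  if (length(bad))
    stop("duplicated chromosome not in reference: ",
         paste(bad, collapse = ", "), call. = FALSE)
  local_seed(seed, {
    out <- lapply(names(ref$chromosomes), function(ch) {
      L <- length(ref$chromosomes[[ch]])
      lambda <- mean_depth * (1 + (ch %in% duplicated_chroms))
      data.table::data.table(strain_id = strain_id, chrom = ch,
                             pos = seq_len(L),
                             depth = stats::rpois(L, lambda))
    })
    tab <- data.table::rbindlist(out)
    data.table::setattr(tab, "class", c("coverage_track", class(tab)))
    tab[]
  })
}

#' Simulate per-strain nucleotide count tables and coverage tracks
#'
#' For every position, depth ~ Poisson(`mean_depth`), doubled on duplicated
#' chromosomes. Base counts are multinomial over A/C/G/T: at an unmutated
#' position the reference base has probability `1 - error_rate` and each
#' non-reference base `error_rate / 3`; at a planted SNP with within-colony
#' fraction f, the alt base takes `f * (1 - error_rate)` of the mass from the
#' reference. Planted insertions/deletions add `ins`/`del` evidence counts
#' (binomial with success probability `f * (1 - error_rate)`), anchored at
#' the base immediately left of the event; base counts at the anchor remain
#' reference-dominated, so `depth == A + C + G + T` always holds.
#'
#' @param ref a `synthetic_reference`
#' @param planted `planted_mutations` table (may have zero rows)
#' @param strain_ids strains to simulate; defaults to strains in `planted`
#' @param mean_depth expected reads per base
#' @param error_rate per-base sequencing error (< 0.05)
#' @param duplicated data.frame/list of (strain_id, chrom) pairs with
#'   whole-chromosome duplications, or NULL
#' @param seed RNG seed, split per strain
#' @return list with `counts` (named list of count data.tables: strain_id,
#'   chrom, pos, A, C, G, T, ins, del, depth) and `coverage` (named list of
#'   `coverage_track`s)
#' @export
simulate_counts <- function(ref, planted, strain_ids = NULL,
                            mean_depth = 30, error_rate = 0.005,
                            duplicated = NULL, seed = 1L) {
  if (error_rate >= 0.05) stop("'error_rate' must be < 0.05", call. = FALSE)
  if (mean_depth < 1) stop("'mean_depth' must be >= 1", call. = FALSE)
  if (is.null(strain_ids))
    strain_ids <- unique(planted$strain_id)
  if (nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      ch <- planted$chrom[k]
      if (!ch %in% names(ref$chromosomes) ||
          planted$pos[k] < 1 ||
          planted$pos[k] > length(ref$chromosomes[[ch]]))
        stop("planted mutation outside reference: ", ch, ":", planted$pos[k],
             call. = FALSE)
    }
  }
  ref_base <- lapply(names(ref$chromosomes), function(ch)
    strsplit(as.character(ref$chromosomes[[ch]]), "")[[1]])
  names(ref_base) <- names(ref$chromosomes)

  counts <- list(); coverage <- list()
  strain_seed <- split_seed(seed, seq_along(strain_ids))
  for (si in seq_along(strain_ids)) {
    s <- strain_ids[si]
    dup <- if (!is.null(duplicated))
      duplicated$chrom[duplicated$strain_id == s] else character(0)
    pl <- planted[planted$strain_id == s, ]
    res <- local_seed(strain_seed[si],
                      simulate_counts_one(ref_base, pl, s, mean_depth,
                                          error_rate, dup))
    counts[[s]] <- res$counts
    coverage[[s]] <- res$coverage
  }
  list(counts = counts, coverage = coverage)
}

# one strain; RNG already seeded
simulate_counts_one <- function(ref_base, planted, strain_id, mean_depth,
                                error_rate, dup_chroms) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(ref_base), function(ch) {
    rb <- ref_base[[ch]]
    L <- length(rb)
    lambda <- mean_depth * (1 + (ch %in% dup_chroms))
    depth <- stats::rpois(L, lambda)
    # per-base alt mass: SNP rows move f*(1-e) of probability to the alt base
    p_alt <- numeric(L); alt_idx <- integer(L)
    ins_p <- numeric(L); del_p <- numeric(L)
    pch <- planted[planted$chrom == ch, ]
    if (nrow(pch)) {
      sn <- pch[pch$type == "snp", ]
      if (nrow(sn)) {
        p_alt[sn$pos] <- sn$fraction * (1 - error_rate)
        alt_idx[sn$pos] <- match(sn$alt_allele, bases)
      }
      ii <- pch[pch$type == "ins", ]
      if (nrow(ii)) ins_p[ii$pos] <- ii$fraction * (1 - error_rate)
      dd <- pch[pch$type == "del", ]
      if (nrow(dd)) del_p[dd$pos] <- dd$fraction * (1 - error_rate)
    }
    # error reads, split uniformly over the three non-reference bases
    err <- stats::rbinom(L, depth, error_rate)
    e1 <- stats::rbinom(L, err, 1 / 3)
    e2 <- stats::rbinom(L, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    cnt <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
    ref_idx <- match(rb, bases)
    # scatter the three error piles onto the non-ref bases
    nonref <- matrix(0L, nrow = L, ncol = 3L)
    nonref[, 1] <- e1; nonref[, 2] <- e2; nonref[, 3] <- e3
    others_tab <- matrix(c(2L, 3L, 4L,   # ref A -> errors on C,G,T
                           1L, 3L, 4L,
                           1L, 2L, 4L,
                           1L, 2L, 3L), nrow = 4L, byrow = TRUE)
    others <- others_tab[ref_idx, , drop = FALSE]
    for (j in 1:3)
      cnt[cbind(seq_len(L), others[, j])] <- nonref[, j]
    cnt[cbind(seq_len(L), ref_idx)] <- depth - err
    # planted SNPs: move alt reads from the reference pile to the alt base
    hit <- which(p_alt > 0 & depth > 0)
    if (length(hit)) {
      alt_reads <- stats::rbinom(length(hit), depth[hit] - err[hit],
                                 p_alt[hit] / (1 - error_rate))
      cnt[cbind(hit, ref_idx[hit])] <-
        cnt[cbind(hit, ref_idx[hit])] - alt_reads
      cnt[cbind(hit, alt_idx[hit])] <-
        cnt[cbind(hit, alt_idx[hit])] + alt_reads
    }
    ins <- integer(L); del <- integer(L)
    hi <- which(ins_p > 0); hd <- which(del_p > 0)
    if (length(hi)) ins[hi] <- stats::rbinom(length(hi), depth[hi], ins_p[hi])
    if (length(hd)) del[hd] <- stats::rbinom(length(hd), depth[hd], del_p[hd])
    # background indel noise at error_rate/10 (indel errors are rarer than
    # base miscalls on short-read data)
    bg <- stats::rbinom(L, depth, error_rate / 10)
    ins <- ins + ifelse(seq_len(L) %% 2L == 0L, bg, 0L)
    del <- del + ifelse(seq_len(L) %% 2L == 1L, bg, 0L)
    data.table::data.table(strain_id = strain_id, chrom = ch, pos = seq_len(L),
                           A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
                           T = cnt[, "T"], ins = ins, del = del,
                           depth = depth)
  })
  tab <- data.table::rbindlist(out)
  data.table::setattr(tab, "class", c("count_table", class(tab)))
  cov <- tab[, c("strain_id", "chrom", "pos", "depth")]
  data.table::setattr(cov, "class", c("coverage_track", class(cov)))
  list(counts = tab[], coverage = cov[])
}
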