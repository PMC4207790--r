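test_that("caller_thresholds enforces its invariant", {
  expect_error(caller_thresholds(min_alt_fraction_strain = 0.5,
                                 max_alt_fraction_ancestor = 0.6), "must be <")
  expect_error(caller_thresholds(min_depth = -1), "min_depth")
})

test_that("strain_qc computes nuclear covered fraction and inclusion", {
  mk_track <- function(depth, strain = "s1") {
    tab <- data.table::data.table(strain_id = strain,
                                  chrom = rep(c("chrI", "chrM"), c(1000, 100)),
                                  pos = c(1:1000, 1:100),
                                  depth = c(depth, rep(0, 100)))
    tab
  }
  r <- strain_qc(mk_track(rep(10, 1000)), mito_chrom = "chrM")
  expect_equal(r$fraction_covered_ge_min_depth, 1.0)
  expect_true(r$included)
  # 75% covered -> excluded at the 0.8 default
  r2 <- strain_qc(mk_track(rep(c(10, 0), c(750, 250))), mito_chrom = "chrM")
  expect_equal(r2$fraction_covered_ge_min_depth, 0.75)
  expect_false(r2$included)
  # mito-only track rejected
  expect_error(strain_qc(mk_track(rep(10, 1000))[chrom == "chrM"],
                         mito_chrom = "chrM"), "nuclear")
  # 39 simulated strains, 11 degraded -> exactly 28 included
  reports <- lapply(1:39, function(i) {
    depth <- if (i <= 11) rep(c(10, 0), c(500, 500)) else rep(10, 1000)
    strain_qc(mk_track(depth, sprintf("s%02d", i)), mito_chrom = "chrM")
  })
  expect_equal(sum(vapply(reports, `[[`, logical(1), "included")), 28L)
})

test_that("call_snps: self-comparison, ancestor-variant exclusion, symmetry", {
  ref <- tiny_reference()
  fx <- planted_fixture(ref, n_snp = 5, seed = 31)
  anc <- fx$sim$counts$ancestor
  expect_equal(nrow(call_snps(anc, anc, verbose = FALSE)), 0L)
  # a site at 50/50 in the ancestor is never called even if fixed in strain
  anc2 <- data.table::copy(anc)
  i <- which(anc2$chrom == "chrI" & anc2$pos == 100)
  data.table::set(anc2, i, c("A", "C", "G", "T", "depth"),
                  list(15L, 15L, 0L, 0L, 30L))
  st <- data.table::copy(anc)
  st$strain_id <- "s1"
  data.table::set(st, i, c("A", "C", "G", "T", "depth"),
                  list(0L, 30L, 0L, 0L, 30L))
  calls <- call_snps(anc2, st, verbose = FALSE)
  expect_false(any(calls$chrom == "chrI" & calls$pos == 100))
  # symmetric null: mutation-free pair yields no calls either way
  sim2 <- simulate_counts(ref, plant_mutations(ref, character(0)),
                          strain_ids = c("a", "b"), seed = 32)
  expect_equal(nrow(call_snps(sim2$counts$a, sim2$counts$b,
                              verbose = FALSE)), 0L)
  expect_equal(nrow(call_snps(sim2$counts$b, sim2$counts$a,
                              verbose = FALSE)), 0L)
})

test_that("call_snps recovers planted SNPs with no false positives", {
  ref <- tiny_reference()
  fx <- planted_fixture(ref, n_snp = 30, seed = 33)
  calls <- call_snps(fx$sim$counts$ancestor, fx$sim$counts$s1,
                     verbose = FALSE)
  planted_key <- paste(fx$planted$chrom, fx$planted$pos)
  called_key <- paste(calls$chrom, calls$pos)
  expect_setequal(called_key, planted_key)                  # sens 1, FDR 0
  m <- merge(calls, fx$planted, by = c("chrom", "pos"))
  expect_equal(m$alt_allele.x, m$alt_allele.y)
  expect_equal(m$ref_allele.x, m$ref_allele.y)
  expect_true(all(calls$alt_fraction >= 0.8))
  # calls are sorted by (chrom, pos)
  expect_false(is.unsorted(order(calls$chrom, calls$pos)))
  # monotonicity: lowering min_alt_fraction_strain never removes a call
  lo <- call_snps(fx$sim$counts$ancestor, fx$sim$counts$s1,
                  caller_thresholds(min_alt_fraction_strain = 0.6),
                  verbose = FALSE)
  expect_true(all(called_key %in% paste(lo$chrom, lo$pos)))
})

test_that("positions absent from the ancestor are skipped, not called", {
  ref <- tiny_reference()
  fx <- planted_fixture(ref, n_snp = 2, seed = 35)
  anc <- fx$sim$counts$ancestor
  pl_key <- paste(fx$planted$chrom, fx$planted$pos)
  drop <- paste(anc$chrom, anc$pos) %in% pl_key[1]
  msgs <- capture_messages(
    calls <- call_snps(anc[!drop, ], fx$sim$counts$s1))
  expect_match(paste(msgs, collapse = " "), "absent-in-ancestor")
  expect_false(pl_key[1] %in% paste(calls$chrom, calls$pos))
  expect_true(pl_key[2] %in% paste(calls$chrom, calls$pos))
})

test_that("call_indels: planted deletion called, homopolymer filtered, clean null", {
  ref <- tiny_reference(seed = 61)
  # plant a deletion inside a gene, in non-repetitive context
  gm <- ref$gene_model[1, ]
  chrom_seq <- strsplit(as.character(ref$chromosomes[[gm$chrom]]), "")[[1]]
  pos <- gm$start + 10L
  while (is_low_complexity(chrom_seq, pos)) pos <- pos + 1L
  pl <- data.table::data.table(strain_id = "s1", chrom = gm$chrom, pos = pos,
                               ref_allele = chrom_seq[pos],
                               alt_allele = NA_character_, type = "del",
                               indel_len = 1L, fraction = 1)
  sim <- simulate_counts(ref, pl, strain_ids = c("ancestor", "s1"),
                         seed = 62)
  calls <- call_indels(sim$counts$ancestor, sim$counts$s1, ref,
                       verbose = FALSE)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "del")
  expect_equal(calls$pos, pos)
  cls <- classify_mutations(calls, ref)
  expect_equal(cls$functional_class, "frameshift")

  # an event inside an 8-bp A-homopolymer is dropped and logged
  ref2 <- tiny_reference(seed = 63)
  s <- as.character(ref2$chromosomes[["chrI"]])
  substr(s, 2001, 2008) <- "AAAAAAAA"
  ref2$chromosomes <- Biostrings::DNAStringSet(
    c(chrI = s, as.character(ref2$chromosomes[-1])))
  pl2 <- data.table::data.table(strain_id = "s1", chrom = "chrI", pos = 2004L,
                                ref_allele = "A", alt_allele = NA_character_,
                                type = "del", indel_len = 1L, fraction = 1)
  sim2 <- simulate_counts(ref2, pl2, strain_ids = c("ancestor", "s1"),
                          seed = 64)
  msgs <- capture_messages(
    calls2 <- call_indels(sim2$counts$ancestor, sim2$counts$s1, ref2))
  expect_match(paste(msgs, collapse = " "), "low-complexity")
  expect_equal(nrow(calls2), 0L)

  # null: no planted indels, error 0.01 -> no calls genome-wide
  big <- make_reference(n_chrom = 2, lengths = c(50000, 50000),
                        genes_per_chrom = 3, mito = FALSE, seed = 65)
  sim3 <- simulate_counts(big, plant_mutations(big, character(0)),
                          strain_ids = c("ancestor", "s1"),
                          error_rate = 0.01, seed = 66)
  expect_equal(nrow(call_indels(sim3$counts$ancestor, sim3$counts$s1, big,
                                verbose = FALSE)), 0L)
})

test_that("codon arithmetic matches the hotspot-locus style examples", {
  # CDS offsets and protein positions as in consensus-sequenced mutants:
  # offset 1174 C>T in a Gln codon -> 392 Q>*; 457 C>G in Arg -> 153 R>G;
  # 893 G>A -> 298 G>D
  cds <- make_cds(400, replace = list("392" = "CAA",   # Q at codon 392
                                      "153" = "CGT",   # R at 153
                                      "298" = "GGT"))  # G at 298
  for (strand in c("+", "-")) {
    ref <- codon_reference(cds, strand = strand)
    g <- ref$gene_model
    cds_pos_to_genomic <- function(off)
      if (strand == "+") g$start + off - 1L else g$end - off + 1L
    mk_call <- function(off, alt_cds) {
      alt <- if (strand == "+") alt_cds else chartr("ACGT", "TGCA", alt_cds)
      calls <- empty_nucleotide_call("s1", g$chrom, cds_pos_to_genomic(off),
                                     alt)
      classify_mutations(calls, ref)
    }
    c1 <- mk_call(1174L, "T")   # CAA -> TAA
    expect_equal(c1$functional_class, "nonsense")
    expect_equal(c1$protein_pos, 392L)
    expect_equal(c(c1$aa_ref, c1$aa_alt), c("Q", "*"))
    c2 <- mk_call(457L, "G")    # CGT -> GGT
    expect_equal(c2$functional_class, "missense")
    expect_equal(c2$protein_pos, 153L)
    expect_equal(c(c2$aa_ref, c2$aa_alt), c("R", "G"))
    c3 <- mk_call(893L, "A")    # GGT -> GAT
    expect_equal(c3$functional_class, "missense")
    expect_equal(c3$protein_pos, 298L)
    expect_equal(c(c3$aa_ref, c3$aa_alt), c("G", "D"))
    # synonymous third-position change: CTG -> CTA (both Leu)
    c4 <- mk_call(3L, "A")
    expect_equal(c4$functional_class, "synonymous")
  }
})

test_that("indel frame rule and gene-boundary refusal", {
  ref <- tiny_reference(seed = 71)
  g <- ref$gene_model[1, ]
  base_call <- empty_nucleotide_call("s1", g$chrom, g$start + 9L, "<DEL>")
  base_call$type <- "del"
  base_call$indel_len <- 3L
  expect_equal(classify_mutations(base_call, ref)$functional_class,
               "inframe_indel")
  base_call$indel_len <- 2L
  expect_equal(classify_mutations(base_call, ref)$functional_class,
               "frameshift")
  # deletion spanning the gene end is refused for manual review
  spill <- empty_nucleotide_call("s1", g$chrom, g$end, "<DEL>")
  spill$type <- "del"; spill$indel_len <- 5L
  out <- classify_mutations(spill, ref)
  expect_true(out$needs_review)
  expect_true(is.na(out$functional_class))
})

test_that("classification agrees with brute-force mutant-CDS translation", {
  set.seed(90)
  ref <- tiny_reference(seed = 91)
  gm <- ref$gene_model
  n <- 1000L
  idx <- sample.int(nrow(gm), n, replace = TRUE)
  ok <- TRUE
  for (k in seq_len(n)) {
    g <- gm[idx[k], ]
    pos <- sample(g$start:g$end, 1L)
    refb <- as.character(Biostrings::subseq(ref$chromosomes[[g$chrom]],
                                            pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    call <- empty_nucleotide_call("s1", g$chrom, pos, alt)
    got <- classify_mutations(call, ref)$functional_class
    want <- oracle_classify_snp(ref, g, pos, alt)
    if (!identical(got, want)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("mixed-colony detection applies the 25%-or-more rule inclusively", {
  thr <- caller_thresholds()
  r <- detect_mixed_colony(data.frame(pos = 1L, minor_fraction = 0.25), thr)
  expect_true(r$heterogeneous)
  r2 <- detect_mixed_colony(data.frame(pos = 1L, minor_fraction = 0.24), thr)
  expect_false(r2$heterogeneous)
  expect_error(detect_mixed_colony(data.frame(pos = 1, minor_fraction = 1.2)),
               "0, 1")
  # colony with two 50/50 sub-clones: both sites mixed
  ref <- tiny_reference(seed = 95)
  pl <- plant_mutations(ref, "s1", n_snp = 2, n_indel = 0, seed = 96)
  pl$fraction <- 0.5
  sim <- simulate_counts(ref, pl, strain_ids = "s1", seed = 97)
  tab <- sim$counts$s1
  sites <- merge(tab, pl[, c("chrom", "pos")], by = c("chrom", "pos"))
  r3 <- detect_mixed_colony(
    data.frame(pos = sites$pos, minor_fraction = minor_fraction(sites)), thr)
  expect_true(r3$heterogeneous)
  expect_equal(nrow(r3$mixed_sites), 2L)
})
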