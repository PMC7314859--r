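# dual-genome concordance and allele assignment

test_that("dual_map_concordance keeps only position-identical unique pairs", {
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 12L)
  a1 <- pairs_from_truth(res$reads, res$truth)
  a2 <- data.table::copy(a1)
  # perturb genome2 mapping for a few reads: position shift / unmapped
  a2$start1[1L] <- a2$start1[1L] + 5L
  a2$mapped[2L] <- FALSE
  a2$unique[3L] <- FALSE
  conc <- dual_map_concordance(a1, a2)
  st <- attr(conc, "status")
  expect_false(any(conc$id %in% a1$id[1:3]))
  expect_equal(sum(!st$concordant), 3L)
  expect_equal(nrow(conc), nrow(a1) - 3L)
})

test_that("assignment matches truth on simulated reads (strict policy)", {
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 13L)
  pairs <- pairs_from_truth(res$reads, res$truth)
  asg <- assign_alleles(pairs, w$snps)
  m <- evaluate_against_truth(asg, res$truth)
  expect_gt(m$accuracy, 0.99)
  expect_gt(m$assignment_rate, 0.2)
  expect_setequal(unique(asg$verdict),
                  intersect(unique(asg$verdict),
                            c("genome1", "genome2", "unassigned",
                              "conflict")))
})

test_that("conversion-blocked and CpG SNPs never vote", {
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 14L)
  pairs <- pairs_from_truth(res$reads, res$truth)
  asg <- assign_alleles(pairs, w$snps, keep_votes = TRUE)
  v <- attr(asg, "votes")
  voted <- v[v$reason %in% c("vote_g1", "vote_g2"), ]
  key <- paste(voted$chrom, voted$snp_pos)
  sn <- w$snps
  snkey <- paste(sn$chrom, sn$pos)
  i <- match(key, snkey)
  expect_false(anyNA(i))
  expect_false(any(sn$in_cpg[i]))
  ot <- voted$strand %in% c("OT", "CTOT")
  expect_true(all(sn$informative_ot[i][ot]))
  expect_true(all(sn$informative_ob[i][!ot]))
})

test_that("hand-built vote cases follow the skip rules", {
  g1 <- tiny_genome()
  snps <- tiny_snps(g1)
  g2 <- reconstruct_alternate_genome(g1, snps)
  snps <- annotate_snp_informativeness(snps, g1, g2)
  # an OT fragment covering the whole 40-bp chromosome, no trimming,
  # all cytosines methylated (no conversion) so the sequence is genomic
  mk_pair <- function(seq1, strand = "OT", id = "x") {
    out <- data.table::data.table(
      id = id, chrom = "chr1", start1 = 0L, start2 = 0L,
      orient1 = if (strand == "OT") "F" else "R",
      orient2 = if (strand == "OT") "R" else "F",
      strand = strand, mm1 = 0L, mm2 = 0L, mapped = TRUE, unique = TRUE,
      read_len = 40L, seq1 = seq1,
      seq2 = strainmeth:::revcomp(seq1),
      qual1 = strrep("I", 40L), qual2 = strrep("I", 40L),
      source = "truth")
    data.table::setattr(out, "class",
                        c("aligned_pairs",
                          class(data.table::data.table())))
    out
  }
  no_trim <- trim_windows(0L, 0L, 0L, 0L)
  # genome1 sequence: votes g1 at the plain SNP (pos 1)
  a <- assign_alleles(mk_pair(g1$seq[["chr1"]]), snps, trim = no_trim,
                      keep_votes = TRUE)
  expect_equal(a$verdict, "genome1")
  v <- attr(a, "votes")
  expect_equal(v$reason[v$snp_pos == 1L], "vote_g1")
  # OT-blocked {C,T} SNP at pos 6 must be conversion_blocked on OT...
  expect_equal(v$reason[v$snp_pos == 6L], "conversion_blocked")
  # CpG SNP at 17 always skipped
  expect_equal(v$reason[v$snp_pos == 17L], "cpg")
  # genome2 sequence on OT: votes g2 at pos 1; pos 10 ({G,A}) is usable on OT
  b <- assign_alleles(mk_pair(g2$seq[["chr1"]]), snps, trim = no_trim,
                      keep_votes = TRUE)
  vb <- attr(b, "votes")
  expect_equal(b$verdict, "genome2")
  expect_equal(vb$reason[vb$snp_pos == 10L], "vote_g2")
  # low-quality base: make qualities poor -> all votes skipped
  p <- mk_pair(g1$seq[["chr1"]])
  p$qual1 <- strrep("#", 40L); p$qual2 <- strrep("#", 40L)
  c_ <- assign_alleles(p, snps, trim = no_trim, keep_votes = TRUE)
  expect_equal(c_$verdict, "unassigned")
  expect_true(all(attr(c_, "votes")$reason == "low_quality" |
                    attr(c_, "votes")$reason %in% c("cpg",
                                                    "conversion_blocked")))
})

test_that("trim windows suppress votes at read ends", {
  g1 <- tiny_genome()
  snps <- tiny_snps(g1)
  g2 <- reconstruct_alternate_genome(g1, snps)
  snps <- annotate_snp_informativeness(snps, g1, g2)
  pair <- data.table::data.table(
    id = "t", chrom = "chr1", start1 = 0L, start2 = 0L,
    orient1 = "F", orient2 = "R", strand = "OT", mm1 = 0L, mm2 = 0L,
    mapped = TRUE, unique = TRUE, read_len = 40L,
    seq1 = g1$seq[["chr1"]], seq2 = strainmeth:::revcomp(g1$seq[["chr1"]]),
    qual1 = strrep("I", 40L), qual2 = strrep("I", 40L), source = "truth")
  data.table::setattr(pair, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  # 5' trim of 5 puts the pos-1 SNP inside the ignored window of both
  # mates' copies (mate 1 5' end covers pos 0..4; mate 2 sees it at its
  # own 3' end... use heavy trims to kill it outright)
  asg <- assign_alleles(pair, snps, trim = trim_windows(20L, 20L, 20L, 0L),
                        keep_votes = TRUE)
  v <- attr(asg, "votes")
  expect_true(all(v$reason[v$snp_pos == 1L] == "trimmed_end"))
})

test_that("strict vs majority policies differ on split votes", {
  # synthetic vote pattern: 3 SNPs voting g1, 1 voting g2
  g <- ref_genome(c(chr1 = paste0("AATTAATTAATTAATTAATTAATTAATTAATTAATTAATT")))
  snps <- snp_table("chr1", c(2L, 10L, 18L, 26L), rep("T", 4L),
                    rep("G", 4L), genome = g)
  g2 <- reconstruct_alternate_genome(g, snps)
  snps <- annotate_snp_informativeness(snps, g, g2)
  # read showing allele1 at 3 SNPs and allele2 at the fourth
  seqv <- g$seq[["chr1"]]
  substr(seqv, 27L, 27L) <- "G"
  pair <- data.table::data.table(
    id = "s", chrom = "chr1", start1 = 0L, start2 = 0L,
    orient1 = "F", orient2 = "R", strand = "OT", mm1 = 0L, mm2 = 0L,
    mapped = TRUE, unique = TRUE, read_len = 40L,
    seq1 = seqv, seq2 = strainmeth:::revcomp(seqv),
    qual1 = strrep("I", 40L), qual2 = strrep("I", 40L), source = "truth")
  data.table::setattr(pair, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  no_trim <- trim_windows(0L, 0L, 0L, 0L)
  strict <- assign_alleles(pair, snps, policy = "strict", trim = no_trim)
  majority <- assign_alleles(pair, snps, policy = "majority",
                             trim = no_trim)
  expect_equal(strict$verdict, "conflict")
  expect_equal(majority$verdict, "genome1")
})

test_that("missing strand is a contract violation", {
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 15L)
  pairs <- pairs_from_truth(res$reads, res$truth)[1:5]
  pairs$strand[2L] <- NA_character_
  expect_error(assign_alleles(pairs, w$snps), "contract")
})
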