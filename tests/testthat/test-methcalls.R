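# methylation extraction, aggregation, coverage I/O

# one fully specified OT pair on the tiny genome, no conversion (all C kept)
tiny_pair <- function(genome = tiny_genome(), convert_pos = integer(0),
                      strand = "OT", id = "m1", L = 40L) {
  s <- genome$seq[["chr1"]]
  for (p in convert_pos) substr(s, p + 1L, p + 1L) <- "T"
  mol <- if (strand %in% c("OT", "CTOT")) s else strainmeth:::revcomp(s)
  r1 <- substr(mol, 1L, L); r2 <- strainmeth:::revcomp(
    substring(mol, nchar(mol) - L + 1L))
  if (strand %in% c("CTOT", "CTOB")) { tmp <- r1; r1 <- r2; r2 <- tmp }
  rev1 <- strand %in% c("OB", "CTOT")
  out <- data.table::data.table(
    id = id, chrom = "chr1", start1 = 0L, start2 = 0L,
    orient1 = ifelse(rev1, "R", "F"), orient2 = ifelse(rev1, "F", "R"),
    strand = strand, mm1 = 0L, mm2 = 0L, mapped = TRUE, unique = TRUE,
    read_len = L, seq1 = r1, seq2 = r2,
    qual1 = strrep("I", L), qual2 = strrep("I", L), source = "truth")
  data.table::setattr(out, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  out
}

no_trim <- trim_windows(0L, 0L, 0L, 0L)

test_that("OT evidence reads C/T at the site C", {
  g <- tiny_genome()
  # CpG sites on chr1: 3, 7, 11, 16, 28, 34; convert sites 7 and 28 to T
  pair <- tiny_pair(g, convert_pos = c(7L, 28L), strand = "OT")
  calls <- call_methylation(pair, g, trim = no_trim)
  calls <- calls[order(calls$pos)]
  expect_equal(calls$pos, c(3L, 7L, 11L, 16L, 28L, 34L))
  expect_equal(calls$meth, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("OB evidence reads G/A at the site G, reported at the C", {
  g <- tiny_genome()
  # on the bottom strand the CpG evidence bases are the genome G's at
  # site+1; converting the bottom-strand C at position (site+1) turns the
  # read base into A.  Build the molecule manually.
  s <- g$seq[["chr1"]]
  bottom <- strainmeth:::revcomp(s)
  # convert the bottom-strand C that pairs with the G at pos 4 (site 3):
  # bottom index of genome pos 4 is 40 - 4 = 36 (1-based)
  substr(bottom, 36L, 36L) <- "T"
  r1 <- substr(bottom, 1L, 40L)
  r2 <- strainmeth:::revcomp(bottom)
  pair <- data.table::data.table(
    id = "ob", chrom = "chr1", start1 = 0L, start2 = 0L,
    orient1 = "R", orient2 = "F", strand = "OB", mm1 = 0L, mm2 = 0L,
    mapped = TRUE, unique = TRUE, read_len = 40L, seq1 = r1, seq2 = r2,
    qual1 = strrep("I", 40L), qual2 = strrep("I", 40L), source = "truth")
  data.table::setattr(pair, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  calls <- call_methylation(pair, g, trim = no_trim)
  calls <- calls[order(calls$pos)]
  expect_equal(calls$pos, c(3L, 7L, 11L, 16L, 28L, 34L))
  expect_equal(calls$meth[calls$pos == 3L], FALSE)
  expect_true(all(calls$meth[calls$pos != 3L]))
})

test_that("trim windows drop end calls and never increase coverage", {
  g <- tiny_genome()
  pair <- tiny_pair(g, strand = "OT")
  full <- call_methylation(pair, g, trim = no_trim)
  trimmed <- call_methylation(pair, g, trim = trim_windows(10L, 10L, 5L, 5L))
  expect_lt(nrow(trimmed), nrow(full))
  # monotonicity on simulated data
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 21L)
  pairs <- pairs_from_truth(res$reads, res$truth)
  cov_of <- function(tr) {
    t <- aggregate_counts(call_methylation(pairs, w$genome, trim = tr))
    sum(t$meth + t$unmeth)
  }
  c0 <- cov_of(no_trim)
  c1 <- cov_of(trim_windows(5L, 5L, 2L, 2L))
  c2 <- cov_of(trim_windows(10L, 10L, 5L, 5L))
  c3 <- cov_of(trim_windows(20L, 20L, 10L, 10L))
  expect_true(c0 >= c1 && c1 >= c2 && c2 >= c3)
})

test_that("excluded (SNP-destroyed) sites give no calls", {
  g <- tiny_genome()
  pair <- tiny_pair(g, strand = "OT")
  calls <- call_methylation(pair, g, trim = no_trim,
                            exclude = data.frame(chrom = "chr1", pos = 7L))
  expect_false(7L %in% calls$pos)
})

test_that("mate overlap is counted once", {
  g <- tiny_genome()
  # 40-bp fragment, 40-bp reads: mates fully overlap; 6 CpGs, not 12 calls
  pair <- tiny_pair(g, strand = "OT")
  calls <- call_methylation(pair, g, trim = no_trim)
  expect_equal(nrow(calls), 6L)
  tab <- aggregate_counts(calls)
  expect_true(all(tab$meth + tab$unmeth == 1L))
})

test_that("aggregation merges strands at the plus-strand C and dedups", {
  w <- small_world()
  cfg <- w$config
  cfg$duplicate_rate <- 0.3
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, cfg,
                             seed = 22L)
  pairs <- pairs_from_truth(res$reads, res$truth)
  calls <- call_methylation(pairs, w$genome)
  with_dup <- aggregate_counts(calls, dedup = FALSE)
  no_dup <- aggregate_counts(calls, dedup = TRUE)
  expect_gt(sum(with_dup$meth + with_dup$unmeth),
            sum(no_dup$meth + no_dup$unmeth))
  # all positions are genuine CpG sites of genome1
  cpg <- index_cpg_sites(w$genome)
  for (ch in unique(no_dup$chrom))
    expect_true(all(no_dup$pos[no_dup$chrom == ch] %in% cpg[[ch]]))
})

test_that("strand restriction keeps only original-bottom evidence", {
  w <- small_world()
  res <- simulate_read_pairs(w$genome, w$genome2, w$methylome, w$config,
                             seed = 23L)
  pairs <- pairs_from_truth(res$reads, res$truth)
  calls <- call_methylation(pairs, w$genome)
  ob <- strand_restrict(calls, "original_bottom_only")
  expect_true(all(ob$strand %in% c("OB", "CTOB")))
  expect_identical(nrow(strand_restrict(calls, "both")), nrow(calls))
})

test_that("filter_table applies the coverage floor", {
  t <- quick_table(c(10L, 20L, 30L), meth = c(3L, 1L, 9L),
                   unmeth = c(1L, 2L, 1L))
  f <- filter_table(t, 4L)
  expect_equal(f$pos, c(10L, 30L))
  expect_error(filter_table(t, 0L), "min_cov")
})

test_that("coverage files round-trip and validate", {
  t <- quick_table(c(3L, 7L), meth = c(2L, 0L), unmeth = c(1L, 5L))
  f <- tempfile(fileext = ".cov")
  write_coverage(t, f)
  expect_equal(readLines(f)[1L], "chr1\t4\t4\t66.7\t2\t1")
  back <- read_coverage(f)
  expect_equal(back$pos, t$pos)
  expect_equal(back$meth, t$meth)
  # inconsistent percentage: counts win, with a warning
  writeLines("chr1\t4\t4\t10.0\t2\t1", f)
  expect_warning(b2 <- read_coverage(f), "inconsistent")
  expect_equal(b2$meth, 2L)
  # malformed row errors with the line number
  writeLines(c("chr1\t4\t4\t66.7\t2\t1", "chr1\tnotanumber"), f)
  expect_error(read_coverage(f), "line 2")
})

test_that("merge_count_tables sums counts site-wise", {
  a <- quick_table(c(1L, 5L), meth = c(1L, 2L), unmeth = c(1L, 0L))
  b <- quick_table(c(5L, 9L), meth = c(3L, 1L), unmeth = c(1L, 1L))
  m <- merge_count_tables(list(a, b))
  expect_equal(m$pos, c(1L, 5L, 9L))
  expect_equal(m$meth, c(1L, 5L, 1L))
  expect_equal(m$unmeth, c(1L, 1L, 1L))
})
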