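# region/gene summaries, target genes, distribution tests

tiny_annotation <- function() {
  genes <- data.frame(
    id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tss = c(5000L, 12000L), tes = c(8000L, 9000L),
    is_pcg = c(TRUE, FALSE), stringsAsFactors = FALSE)
  gene_annotation(genes,
                  cgis = data.frame(chrom = "chr1", start = 4500L,
                                    end = 5500L),
                  chrom_class = c(chr1 = "autosome", chrX = "X"))
}

test_that("region_mean is the unweighted site mean with floors", {
  t <- quick_table(c(100L, 110L, 120L, 500L),
                   meth = c(2L, 4L, 6L, 5L), unmeth = c(8L, 6L, 4L, 5L))
  iv <- data.frame(chrom = "chr1", start = 90L, end = 130L)
  expect_equal(region_mean(t, iv), 0.4)           # (0.2+0.4+0.6)/3
  # below min_sites: undefined
  expect_true(is.na(region_mean(t, iv, min_sites = 4L)))
  # coverage floor excludes low sites
  t2 <- quick_table(c(100L, 110L, 120L), meth = c(2L, 4L, 1L),
                    unmeth = c(8L, 6L, 1L))
  expect_true(is.na(region_mean(t2, iv, min_cov = 5L, min_sites = 3L)))
  # no overlapping CpG: undefined; empty interval list: empty result
  expect_true(is.na(region_mean(t, data.frame(chrom = "chr1",
                                              start = 0L, end = 10L))))
  expect_length(region_mean(t, iv[0, ]), 0L)
})

test_that("region_mean is invariant under subdivision + recombination", {
  w <- small_world()
  tab <- simulate_count_tables(w$methylome, "WT", coverage = 20,
                               n_rep = 1L, seed = 41L)[[1L]]
  iv <- data.frame(chrom = "chr1", start = 10000L, end = 30000L)
  halves <- data.frame(chrom = "chr1", start = c(10000L, 20000L),
                       end = c(20000L, 30000L))
  whole <- region_mean(tab, iv, min_sites = 1L)
  parts <- region_mean(tab, halves, min_sites = 1L)
  # site counts for the recombination weights
  d <- as.data.frame(filter_table(tab, 5L))
  d <- d[d$chrom == "chr1", ]
  n1 <- sum(d$pos >= 10000L & d$pos < 20000L)
  n2 <- sum(d$pos >= 20000L & d$pos < 30000L)
  expect_equal(whole, (n1 * parts[1L] + n2 * parts[2L]) / (n1 + n2))
})

test_that("gene summaries use TSS +/- 1000 and min..max body", {
  ann <- tiny_annotation()
  pos <- c(4200L, 5000L, 5800L, 6500L, 7000L, 7500L,   # gA tss + body
           11200L, 11800L, 12090L, 10000L, 9500L, 9200L)
  t <- quick_table(sort(pos), meth = 8L, unmeth = 2L)
  g <- ref_genome(c(chr1 = strrep("AT", 10000L)),
                  chrom_class = c(chr1 = "autosome"))
  s <- gene_summaries(t, ann, g)
  expect_equal(s$gene_id, c("gA", "gB"))
  expect_equal(s$tss_mean, c(0.8, 0.8))
  expect_equal(s$body_mean, c(0.8, 0.8))
  # minus-strand gene gB: tss window is [11000, 13000), body [9000, 12000)
  t2 <- quick_table(c(11100L, 11500L, 12500L), meth = c(10L, 0L, 10L),
                    unmeth = c(0L, 10L, 0L))
  s2 <- gene_summaries(t2, ann, g, min_sites = 3L)
  expect_equal(s2$tss_mean[2L], 2 / 3)
  expect_true(is.na(s2$tss_mean[1L]))
})

test_that("windows clipped at chromosome ends warn", {
  ann <- gene_annotation(data.frame(
    id = "g", chrom = "chr1", strand = "+", tss = 1500L, tes = 1900L,
    is_pcg = FALSE), chrom_class = c(chr1 = "autosome"))
  g <- ref_genome(c(chr1 = strrep("ACGT", 500L)),
                  chrom_class = c(chr1 = "autosome"))
  t <- quick_table(c(1600L, 1700L, 1800L), meth = 1L, unmeth = 1L)
  expect_warning(gene_summaries(t, ann, g), "clip")
})

test_that("target genes come from overlapping WT_gt_KO regions only", {
  ann <- tiny_annotation()
  dmrs <- data.frame(
    chrom = "chr1", start = c(6000L, 9500L, 30000L),
    end = c(6200L, 9700L, 30200L),
    direction = c("WT_gt_KO", "KO_gt_WT", "WT_gt_KO"))
  # gA body hit by a WT_gt_KO region; gB hit only by KO_gt_WT; the third
  # region is intergenic
  expect_equal(identify_target_genes(dmrs, ann), "gA")
  expect_equal(identify_target_genes(dmrs, ann, direction = "KO_gt_WT"),
               "gB")
  # promoter flank counts toward the footprint
  dmr2 <- data.frame(chrom = "chr1", start = 4100L, end = 4200L,
                     direction = "WT_gt_KO")
  expect_equal(identify_target_genes(dmr2, ann), "gA")
  expect_length(identify_target_genes(dmrs[0, ], ann), 0L)
})

test_that("threshold_diff_genes joins by id and applies |diff| >= 0.1", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  tss_mean = c(0.50, 0.30, NA))
  b <- data.frame(gene_id = c("g1", "g2", "g4"),
                  tss_mean = c(0.38, 0.21, 0.5))
  r <- threshold_diff_genes(a, b)
  expect_equal(r$gene_id, "g1")          # diff 0.12 kept, 0.09 dropped
  expect_equal(r$direction, "A_gt_B")
  expect_warning(threshold_diff_genes(a[0, ], b), "shared")
})

test_that("expressed_promoter_filter is strict and joins expression", {
  s <- data.frame(gene_id = c("g1", "g2", "g3"),
                  tss_mean = c(0.16, 0.15, NA))
  expr <- data.frame(gene_id = c("g1", "gZ"), fpkm = c(12.5, 1))
  expect_message(r <- expressed_promoter_filter(s, expr), "skip")
  expect_equal(r$gene_id, "g1")          # 0.15 exactly and NA excluded
  expect_equal(r$fpkm, 12.5)
  r2 <- expressed_promoter_filter(s)
  expect_true(is.na(r2$fpkm))
})

test_that("cgi_split partitions filtered site levels by class", {
  ann <- tiny_annotation()
  t <- quick_table(c(4600L, 5200L, 8000L), meth = c(1L, 2L, 3L),
                   unmeth = c(9L, 8L, 7L))
  sp <- cgi_split(t, ann)
  expect_length(sp$cgi, 2L)
  expect_length(sp$non_cgi, 1L)
  expect_equal(sort(c(sp$cgi, sp$non_cgi)),
               sort(t$meth / (t$meth + t$unmeth)))
  # chromosome filter
  t2 <- cpg_count_table(data.frame(
    chrom = c("chr1", "chrX"), pos = c(4600L, 100L), meth = c(1L, 1L),
    unmeth = c(1L, 1L)))
  spx <- cgi_split(t2, ann, chromosome_filter = "X")
  expect_length(c(spx$cgi, spx$non_cgi), 1L)
  expect_error(cgi_split(t2, ann, chromosome_filter = "Z"), "unknown")
})

test_that("compare_groups matches small-sample enumeration oracles", {
  # MWU: A={1,2,3}, B={4,5,6}: U = 0, exact one-sided 1/20, two-sided 0.1
  m <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mwu")
  expect_equal(m$statistic, 0)
  expect_equal(m$p.value, 0.1)
  expect_match(m$method, "exact")
  # identical samples, KS: D = 0
  k <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "ks")
  expect_equal(k$statistic, 0)
  # signed-rank exact oracle, n = 3, all positive: V = 6,
  # two-sided p = 2 * P(V >= 6) = 2/8
  wl <- compare_groups(c(2, 3, 4), c(1, 1, 1), test = "wilcoxon")
  expect_equal(wl$statistic, 6)
  expect_equal(wl$p.value, 0.25)
  # exhaustive MWU check against pwilcox for all 4+4 rank splits
  a <- c(1, 4, 6, 7); b <- c(2, 3, 5, 8)
  mm <- compare_groups(a, b, test = "mwu")
  U <- sum(rank(c(a, b))[1:4]) - 4 * 5 / 2
  p_exact <- min(1, 2 * min(pwilcox(U, 4, 4), 1 - pwilcox(U - 1, 4, 4)))
  expect_equal(mm$p.value, p_exact)
})

test_that("compare_groups degenerate and contract cases", {
  expect_warning(r <- compare_groups(c(1, 2), c(1, 2), test = "wilcoxon"),
                 "zero")
  expect_equal(r$p.value, 1)
  expect_error(compare_groups(1:3, 1:4, test = "wilcoxon"), "equal-length")
  expect_error(compare_groups(1:3, 1:3, test = "mwu", paired = TRUE),
               "paired")
  expect_error(compare_groups(1:3, 1:3, test = "wilcoxon", paired = FALSE),
               "paired")
  # large samples switch to the normal approximation
  set.seed(1)
  big <- compare_groups(rnorm(200), rnorm(200), test = "mwu")
  expect_match(big$method, "approximation")
})
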