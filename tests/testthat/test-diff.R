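# beta-binomial Wald test, FDR, tile and region calling

test_that("dml_test matches the hand-computed Wald oracle", {
  # group A: two replicates k=8/n=10 and k=8/n=10; group B: k=2,2 / n=10,10
  # with phi fixed at 0.1:
  #   mu1 = 16/20 = 0.8, var1 = 2 * 10*0.8*0.2*(1+9*0.1) / 20^2 = 0.0152
  #   mu2 = 0.2, var2 = 0.0152, z = 0.6 / sqrt(0.0304)
  a <- lapply(1:2, function(i) quick_table(10L, meth = 8L, unmeth = 2L))
  b <- lapply(1:2, function(i) quick_table(10L, meth = 2L, unmeth = 8L))
  rec <- dml_test(a, b, phi_override = 0.1)
  z <- 0.6 / sqrt(2 * (2 * 10 * 0.8 * 0.2 * 1.9 / 400))
  expect_equal(rec$diff, 0.6)
  expect_equal(rec$stat, z, tolerance = 1e-12)
  expect_equal(rec$pval, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # phi = 0 reduces to the binomial variance
  rec0 <- dml_test(a, b, phi_override = 0)
  z0 <- 0.6 / sqrt(2 * 0.8 * 0.2 / 20)
  expect_equal(rec0$stat, z0, tolerance = 1e-12)
})

test_that("zero difference with zero variance gives z = 0, p = 1", {
  a <- quick_table(c(1L, 5L), meth = c(10L, 0L), unmeth = c(0L, 10L))
  rec <- dml_test(list(a), list(a), phi_override = 0)
  expect_equal(rec$stat, c(0, 0))
  expect_equal(rec$pval, c(1, 1))
})

test_that("dml_test is antisymmetric under group swap", {
  w <- small_world()
  a <- simulate_count_tables(w$methylome, "WT", coverage = 20, phi = 0.05,
                             n_rep = 2L, seed = 31L)
  b <- simulate_count_tables(w$methylome, "KO3A", coverage = 20, phi = 0.05,
                             n_rep = 2L, seed = 32L)
  ab <- dml_test(a, b)
  ba <- dml_test(b, a)
  expect_equal(ab$stat, -ba$stat)
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$pval, ba$pval)
})

test_that("bh_fdr matches p.adjust and rejects bad input", {
  p <- c(0.01, 0.02, 0.03, 0.5, 1)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  expect_equal(bh_fdr(c(0.03, 0.03, 0.03)), rep(0.03, 3L))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(numeric(0)), numeric(0))
})

test_that("single-replicate groups use the local dispersion window", {
  w <- small_world()
  a <- simulate_count_tables(w$methylome, "WT", coverage = 20, phi = 0.05,
                             n_rep = 1L, seed = 33L)
  b <- simulate_count_tables(w$methylome, "KO3A", coverage = 20, phi = 0.05,
                             n_rep = 1L, seed = 34L)
  rec <- dml_test(a, b, smooth_span = 500L)
  expect_true(all(rec$phi1 >= 0))
  expect_true(any(rec$phi1 > 0))
  # smooth_span = 0 falls back to binomial variances (phi = 0)
  rec0 <- dml_test(a, b, smooth_span = 0L)
  expect_true(all(rec0$phi1 == 0))
})

test_that("DMT calling hits planted 0.5 differences and nothing at 0.3", {
  set.seed(101)
  size <- 1000L
  n_tiles <- 60L
  sites_per <- 12L
  pos <- as.integer(outer(seq(0L, by = 80L, length.out = sites_per),
                          (seq_len(n_tiles) - 1L) * size, "+"))
  tile_of <- rep(seq_len(n_tiles), each = sites_per)
  # tiles 1..15 diff 0.5; 16..30 diff 0.3; rest null
  p_wt <- rep(0.8, length(pos))
  p_ko <- ifelse(tile_of <= 15L, 0.3,
                 ifelse(tile_of <= 30L, 0.5, 0.8))
  mk <- function(p, seed) {
    set.seed(seed)
    n <- rpois(length(pos), 30)
    k <- rbinom(length(pos), n, p)
    quick_table(pos, meth = k, unmeth = n - k)
  }
  samples <- list(mk(p_wt, 1), mk(p_wt, 2), mk(p_ko, 3), mk(p_ko, 4))
  res <- call_dmts(samples, groups = c("WT", "WT", "KO", "KO"),
                   params = test_params())
  called <- sort(unique(res$dmt$start %/% size + 1L))
  truth <- 1:15
  expect_gte(length(intersect(called, truth)) / length(truth), 0.9)
  expect_gte(length(intersect(called, truth)) / max(length(called), 1L),
             0.9)
  # the 0.3-difference tiles are never called (threshold property)
  expect_length(intersect(called, 16:30), 0L)
})

test_that("tile partition is disjoint and tiles respect eligibility", {
  w <- small_world()
  tabs <- simulate_count_tables(w$methylome, "WT", coverage = 15,
                                n_rep = 2L, seed = 35L)
  res <- call_dmts(tabs, groups = c("a", "b"), params = test_params())
  rec <- res$records
  # tile starts are multiples of the tile size, unique per chromosome
  expect_true(all(rec$start %% 1000L == 0L))
  expect_false(anyDuplicated(rec[, c("chrom", "start")]) > 0)
  # every CpG site belongs to exactly one tile
  tile_idx <- w$methylome$pos %/% 1000L
  expect_true(all(tile_idx >= 0))
  expect_equal(length(tile_idx), nrow(w$methylome))
})

test_that("DMR calling recovers planted dense regions with high Jaccard", {
  set.seed(7)
  # 12 planted regions of 20 CpGs spaced 50 bp, separated by null stretches
  region_len <- 20L * 50L
  gap <- 4000L
  starts <- (seq_len(12L) - 1L) * (region_len + gap) + 2000L
  pos <- integer(0); inside <- logical(0)
  for (s in starts) {
    pos <- c(pos, seq(s, by = 50L, length.out = 20L))
    inside <- c(inside, rep(TRUE, 20L))
    bg <- seq(s + region_len + 500L, by = 300L, length.out = 8L)
    pos <- c(pos, bg); inside <- c(inside, rep(FALSE, 8L))
  }
  o <- order(pos); pos <- as.integer(pos[o]); inside <- inside[o]
  p_wt <- rep(0.8, length(pos))
  p_ko <- ifelse(inside, 0.4, 0.8)
  mk <- function(p, seed) {
    set.seed(seed)
    n <- rpois(length(pos), 50)
    k <- rbinom(length(pos), n, p)
    quick_table(pos, meth = k, unmeth = n - k)
  }
  rec <- dml_test(list(mk(p_wt, 1), mk(p_wt, 2)),
                  list(mk(p_ko, 3), mk(p_ko, 4)))
  dmrs <- call_dmrs(rec, test_params())
  expect_gte(nrow(dmrs), 10L)
  expect_true(all(dmrs$direction == "WT_gt_KO"))
  planted <- data.frame(chrom = "chr1", start = starts,
                        end = starts + 19L * 50L + 2L)
  j <- interval_jaccard(dmrs[, c("chrom", "start", "end")], planted)
  expect_gte(j, 0.8)
})

test_that("call_dmrs rejects unsorted records and handles empties", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 50L), mu1 = 0.5,
                    mu2 = 0.5, diff = 0, phi1 = 0, phi2 = 0, n1 = 10,
                    n2 = 10, stat = 0, pval = 1, fdr = 1)
  expect_error(call_dmrs(rec), "sorted")
  empty <- rec[0, ]
  expect_equal(nrow(call_dmrs(empty)), 0L)
})

test_that("category fractions sum to one and use the stated bins", {
  t <- quick_table(1:5 * 10L, meth = c(10L, 9L, 5L, 2L, 0L),
                   unmeth = c(0L, 1L, 5L, 8L, 10L))
  f <- methylation_categories(t)
  expect_equal(sum(f), 1)
  expect_equal(unname(f["hyper"]), 2 / 5)         # 1.0 and 0.9
  expect_equal(unname(f["intermediate"]), 2 / 5)  # 0.5 and 0.2 (inclusive)
  expect_equal(unname(f["hypo"]), 1 / 5)
  expect_error(methylation_categories(
    quick_table(integer(0), integer(0), integer(0), chrom = character(0))),
    "empty")
})

test_that("chromosome log2FC of a sample against itself is exactly zero", {
  w <- small_world()
  tab <- simulate_count_tables(w$methylome, "WT", coverage = 20,
                               n_rep = 1L, seed = 36L)[[1L]]
  fc <- chromosome_log2fc(tab, tab, min_sites = 10L)
  expect_true(all(fc$log2fc == 0))
})
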