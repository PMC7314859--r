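# feature-level methylation summaries and group comparisons

#' Mean methylation per region
#'
#' For each query interval, the unweighted mean of the per-site methylation
#' levels of covered CpGs inside it.  Sites below \code{min_cov} are
#' dropped first; regions retaining fewer than \code{min_sites} sites get
#' \code{NA}.
#'
#' @param table \code{cpg_count_table}.
#' @param regions data.frame with chrom/start/end (0-based half-open).
#' @param min_cov per-site coverage floor (default 5).
#' @param min_sites minimal retained sites per region (default 3).
#' @return numeric vector, one mean per region row.
#' @export
region_mean <- function(table, regions, min_cov = 5L, min_sites = 3L) {
  d <- data.table::as.data.table(as.data.frame(table))
  d <- d[meth + unmeth >= min_cov]
  out <- rep(NA_real_, nrow(regions))
  if (nrow(d) == 0L || nrow(regions) == 0L) return(out)
  d[, level := meth / (meth + unmeth)]
  q <- data.table::data.table(row = seq_len(nrow(regions)),
                              chrom = as.character(regions$chrom),
                              start = as.integer(regions$start),
                              end = as.integer(regions$end))
  ov <- d[q, on = .(chrom, pos >= start, pos < end), nomatch = NULL,
          .(row = i.row, level = x.level)]
  if (nrow(ov) == 0L) return(out)
  agg <- ov[, .(m = mean(level), n = .N), by = row]
  agg <- agg[n >= min_sites]
  out[agg$row] <- agg$m
  out
}

#' Promoter and gene-body methylation per gene
#'
#' Promoter = TSS +/- \code{flank} bp (strand-independent window around the
#' annotated TSS); gene body = the [min, max) span of TSS and TES.  Windows
#' extending past a chromosome end are clipped with a warning.
#'
#' @param table \code{cpg_count_table}.
#' @param annotation \code{gene_annotation}.
#' @param genome \code{ref_genome} (for end clipping).
#' @param flank promoter half-width in bp (default 1000).
#' @param min_cov,min_sites forwarded to \code{\link{region_mean}}.
#' @return data.frame: gene_id, chrom, strand, is_pcg, tss_mean, body_mean.
#' @export
gene_summaries <- function(table, annotation, genome, flank = 1000L,
                           min_cov = 5L, min_sites = 3L) {
  g <- annotation$genes
  tss <- gene_tss_intervals(g, flank = flank)
  body <- gene_body_intervals(g)
  lens <- genome$length[tss$chrom]
  clip <- tss$end > lens | body$end > lens
  if (any(clip)) {
    warning(sum(clip), " window(s) clipped at a chromosome end")
    tss$end <- pmin(tss$end, lens)
    body$end <- pmin(body$end, lens)
  }
  data.frame(gene_id = g$id, chrom = g$chrom, strand = g$strand,
             is_pcg = g$is_pcg,
             tss_mean = region_mean(table, tss, min_cov, min_sites),
             body_mean = region_mean(table, body, min_cov, min_sites),
             stringsAsFactors = FALSE)
}

#' Genes targeted by hypomethylated regions
#'
#' A gene is a target when its body or promoter window overlaps at least
#' one region of the requested direction (default: regions hypomethylated
#' in the knockout, i.e. \code{WT_gt_KO}).
#'
#' @param dmrs \code{dmr_set} from \code{\link{call_dmrs}} (or any
#'   chrom/start/end data.frame, optionally with a direction column).
#' @param annotation \code{gene_annotation}.
#' @param direction keep only regions with this direction label; NULL keeps
#'   all.
#' @param flank promoter half-width included in the gene footprint.
#' @return character vector of target gene ids (sorted, unique).
#' @export
identify_target_genes <- function(dmrs, annotation,
                                  direction = "WT_gt_KO", flank = 1000L) {
  d <- as.data.frame(dmrs)
  if (!is.null(direction) && !is.null(d$direction))
    d <- d[d$direction == direction, , drop = FALSE]
  if (nrow(d) == 0L) return(character(0))
  g <- annotation$genes
  # footprint = gene extent extended by the promoter flank on the TSS side
  body <- gene_body_intervals(g)
  plus <- g$strand == "+"
  foot <- data.frame(chrom = body$chrom,
                     start = ifelse(plus, pmax(0L, body$start - flank),
                                    body$start),
                     end = ifelse(plus, body$end, body$end + flank))
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(foot), intervals_to_granges(d))
  sort(unique(g$id[S4Vectors::queryHits(hits)]))
}

#' Genes with a promoter methylation difference of at least a threshold
#'
#' Genes are matched by id; genes missing (or with an undefined mean) in
#' either summary are excluded.
#'
#' @param summA,summB \code{\link{gene_summaries}} outputs on a shared gene
#'   universe.
#' @param column which summary column to compare ("tss_mean" or
#'   "body_mean").
#' @param min_abs_diff minimal absolute difference (default 0.1).
#' @return data.frame gene_id, mean_a, mean_b, diff, direction
#'   ("A_gt_B"/"B_gt_A") for passing genes.
#' @export
threshold_diff_genes <- function(summA, summB, column = "tss_mean",
                                 min_abs_diff = 0.1) {
  m <- merge(summA[, c("gene_id", column)], summB[, c("gene_id", column)],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    warning("no shared genes between the two summaries")
    return(data.frame(gene_id = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), diff = numeric(0),
                      direction = character(0)))
  }
  a <- m[[paste0(column, "_a")]]; b <- m[[paste0(column, "_b")]]
  d <- a - b
  keep <- !is.na(d) & abs(d) >= min_abs_diff
  data.frame(gene_id = m$gene_id[keep], mean_a = a[keep], mean_b = b[keep],
             diff = d[keep],
             direction = ifelse(d[keep] > 0, "A_gt_B", "B_gt_A"),
             stringsAsFactors = FALSE)
}

#' Genes with a methylated promoter, joined to expression values
#'
#' Keeps genes whose promoter mean is strictly greater than
#' \code{min_tss_meth} (default 0.15, i.e. >15%; genes with an undefined
#' promoter mean fail) and joins the supplied expression table for
#' reporting.  Expression ids absent from the summaries are logged and
#' skipped; retained genes without an expression value get \code{NA}.
#' Expression values are consumed, never computed.
#'
#' @param summaries \code{\link{gene_summaries}} output for the reference
#'   condition.
#' @param expression_table optional data.frame (gene_id, fpkm).
#' @param min_tss_meth methylation floor (strict).
#' @return data.frame gene_id, tss_mean, fpkm for retained genes.
#' @export
expressed_promoter_filter <- function(summaries, expression_table = NULL,
                                      min_tss_meth = 0.15) {
  keep <- !is.na(summaries$tss_mean) & summaries$tss_mean > min_tss_meth
  out <- data.frame(gene_id = summaries$gene_id[keep],
                    tss_mean = summaries$tss_mean[keep],
                    fpkm = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(expression_table)) {
    unknown <- !expression_table$gene_id %in% summaries$gene_id
    if (any(unknown))
      msg(sum(unknown), " expression id(s) not in the gene summaries; ",
          "skipped")
    i <- match(out$gene_id, expression_table$gene_id)
    out$fpkm <- expression_table$fpkm[i]
  }
  out
}

#' Split site-level methylation by CpG-island membership
#'
#' Partitions the per-site levels of a (filtered) count table into CGI and
#' non-CGI sets, optionally restricted to one chromosome class.  The two
#' partitions are disjoint and their union is the (filtered) site set.
#'
#' @param table \code{cpg_count_table}.
#' @param annotation \code{gene_annotation} (uses \code{cgis} and
#'   \code{chrom_class}).
#' @param chromosome_filter optional chromosome class to keep ("X" or
#'   "autosome"); unknown values are a parameter error.
#' @return list(cgi, non_cgi) of numeric site levels.
#' @export
cgi_split <- function(table, annotation, chromosome_filter = NULL) {
  d <- as.data.frame(table)
  if (!is.null(chromosome_filter)) {
    if (!chromosome_filter %in% annotation$chrom_class)
      stop("unknown chromosome class: ", chromosome_filter)
    d <- d[annotation$chrom_class[d$chrom] == chromosome_filter, ,
           drop = FALSE]
  }
  lvl <- ifelse(d$meth + d$unmeth > 0, d$meth / (d$meth + d$unmeth),
                NA_real_)
  if (nrow(d) == 0L) return(list(cgi = numeric(0), non_cgi = numeric(0)))
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos + 1L,
                                                         width = 1L))
  in_cgi <- suppressWarnings(GenomicRanges::countOverlaps(
    gr, intervals_to_granges(annotation$cgis))) > 0
  list(cgi = lvl[in_cgi], non_cgi = lvl[!in_cgi])
}

#' Two-sample and paired distribution tests
#'
#' \code{ks}: two-sample Kolmogorov-Smirnov via \code{ks.test}.
#' \code{mwu}: Mann-Whitney U; the exact null via \code{pwilcox} when
#' \code{length(a) * length(b) <= 1e4} and there are no ties, otherwise the
#' normal approximation with tie correction (via \code{wilcox.test}).
#' \code{wilcoxon}: paired signed-rank; zero differences are dropped
#' (Wilcoxon's convention), exact via \code{psignrank} when the number of
#' nonzero pairs is <= 25 and ranks are untied, otherwise the normal
#' approximation.  Two-sided p-values are computed by doubling the smaller
#' tail (capped at 1).
#'
#' @param a,b numeric vectors (equal length for \code{wilcoxon}).
#' @param test "ks", "mwu" or "wilcoxon".
#' @param paired must be TRUE for \code{wilcoxon} and FALSE otherwise.
#' @return list(statistic, p.value, method).
#' @export
compare_groups <- function(a, b, test = c("ks", "mwu", "wilcoxon"),
                           paired = test == "wilcoxon") {
  test <- match.arg(test)
  if (test == "wilcoxon" && !paired)
    stop("the signed-rank test is paired; call with paired = TRUE")
  if (test != "wilcoxon" && paired)
    stop("paired comparison requires test = \"wilcoxon\"")
  if (test != "wilcoxon") {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (test == "ks") {
    if (!length(a) || !length(b)) stop("empty sample")
    k <- suppressWarnings(ks.test(a, b))
    return(list(statistic = unname(k$statistic), p.value = k$p.value,
                method = "two-sample KS"))
  }
  if (test == "mwu") {
    if (!length(a) || !length(b)) stop("empty sample")
    nA <- length(a); nB <- length(b)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- anyDuplicated(c(a, b)) > 0L
    if (!ties && nA * nB <= 1e4) {
      lower <- pwilcox(U, nA, nB)
      upper <- 1 - pwilcox(U - 1, nA, nB)
      p <- min(1, 2 * min(lower, upper))
      return(list(statistic = U, p.value = p, method = "exact MWU"))
    }
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    return(list(statistic = U, p.value = w$p.value,
                method = "normal-approximation MWU"))
  }
  if (length(a) != length(b))
    stop("paired test requires equal-length vectors")
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; degenerate signed-rank test")
    return(list(statistic = 0, p.value = 1,
                method = "signed-rank (all differences zero)"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    lower <- psignrank(V, n)
    upper <- 1 - psignrank(V - 1, n)
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = V, p.value = p, method = "exact signed-rank"))
  }
  w <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                    correct = TRUE))
  list(statistic = V, p.value = w$p.value,
       method = "normal-approximation signed-rank")
}
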