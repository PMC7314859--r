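# two-group beta-binomial Wald testing, tile (DMT) and region (DMR) calling

#' Test and calling parameters
#'
#' Bundles every threshold of the tile/region callers.  Defaults are the
#' analysis' published operating points: nonoverlapping 1-kb tiles with
#' pooled coverage >= 10 in every sample, tile significance FDR < 0.01 with
#' methylation difference (group1 - group2) > 0.4; region calling with
#' delta = 0.2, p.threshold = 1e-5 and minCG = 10 on >= 50x capture data;
#' site-level presets use FDR < 0.05.
#'
#' @param tile_size,tile_min_cov,tile_fdr,tile_diff tile (DMT) parameters.
#' @param dmr_delta,dmr_p,dmr_minCG,dmr_merge_gap,dmr_minlen,dmr_pct_sig
#'   region (DMR) parameters.
#' @param site_min_cov per-site coverage floor (5 whole-genome, 50 capture).
#' @param epi_fdr FDR for site-level differential loci presets.
#' @param smooth_span bp window for single-replicate dispersion estimation
#'   (0 disables local estimation).
#' @return list of class \code{test_params}.
#' @export
test_params <- function(tile_size = 1000L, tile_min_cov = 10L,
                        tile_fdr = 0.01, tile_diff = 0.4,
                        dmr_delta = 0.2, dmr_p = 1e-5, dmr_minCG = 10L,
                        dmr_merge_gap = 100L, dmr_minlen = 50L,
                        dmr_pct_sig = 0.5, site_min_cov = 5L,
                        epi_fdr = 0.05, smooth_span = 500L) {
  p <- as.list(environment())
  if (any(unlist(p[c("tile_size", "tile_min_cov", "dmr_minCG",
                     "dmr_merge_gap", "dmr_minlen", "site_min_cov")]) <= 0))
    stop("size/coverage parameters must be positive")
  if (any(unlist(p[c("tile_fdr", "tile_diff", "dmr_delta", "dmr_pct_sig",
                     "epi_fdr")]) <= 0) ||
      any(unlist(p[c("tile_fdr", "tile_diff", "dmr_delta", "dmr_pct_sig",
                     "epi_fdr")]) >= 1))
    stop("rates and deltas must lie in (0, 1)")
  class(p) <- "test_params"
  p
}

# align a list of count tables onto the union of their sites; returns
# matrices k (methylated) and n (coverage) with site keys
stack_tables <- function(tables) {
  dts <- lapply(seq_along(tables), function(i) {
    d <- data.table::as.data.table(as.data.frame(tables[[i]]))
    d[, rep := i]
    d
  })
  long <- data.table::rbindlist(dts)
  sites <- unique(long[, .(chrom, pos)])
  data.table::setkeyv(sites, c("chrom", "pos"))
  k <- matrix(0, nrow(sites), length(tables))
  n <- matrix(0, nrow(sites), length(tables))
  for (i in seq_along(tables)) {
    d <- dts[[i]]
    j <- sites[d[, .(chrom, pos)], on = c("chrom", "pos"), which = TRUE]
    k[j, i] <- d$meth
    n[j, i] <- d$meth + d$unmeth
  }
  list(sites = sites, k = k, n = n)
}

# method-of-moments beta-binomial dispersion per site, shrunk 50:50 toward
# the genome-wide mean of the raw estimates (which is unbiased; the raw
# per-site values are chi-square-noisy with few replicates)
dispersion_mom <- function(k, n) {
  m <- ncol(k)
  N <- rowSums(n); K <- rowSums(k)
  p <- ifelse(N > 0, K / N, 0)
  pq <- p * (1 - p)
  nbar <- rowMeans(n)
  X2 <- rowSums(ifelse(n > 0, (k - n * p)^2 / pmax(n * pq, 1e-12), 0))
  raw <- (X2 / (m - 1) - 1) / pmax(nbar - 1, 1)
  raw[!is.finite(raw) | pq == 0] <- 0
  anchor <- max(0, mean(raw))
  pmax(0, 0.5 * pmax(raw, 0) + 0.5 * anchor)
}

# single-replicate dispersion: treat sites within +/- span/2 as replicates
# of a local level, method-of-moments across the window, same shrinkage
dispersion_local <- function(sites, k, n, span) {
  kk <- as.numeric(k); nn <- as.numeric(n)
  raw <- numeric(length(kk))
  half <- span / 2
  for (ch in unique(sites$chrom)) {
    ii <- which(sites$chrom == ch)
    pos <- sites$pos[ii]
    csk <- cumsum(kk[ii]); csn <- cumsum(nn[ii])
    csk2 <- cumsum(ifelse(nn[ii] > 0, kk[ii]^2 / nn[ii], 0))
    lo <- findInterval(pos - half - 1, pos) + 1L
    hi <- findInterval(pos + half, pos)
    w <- hi - lo + 1L
    sk <- csk[hi] - ifelse(lo > 1L, csk[lo - 1L], 0)
    sn <- csn[hi] - ifelse(lo > 1L, csn[lo - 1L], 0)
    sk2 <- csk2[hi] - ifelse(lo > 1L, csk2[lo - 1L], 0)
    pbar <- ifelse(sn > 0, sk / sn, 0)
    pq <- pbar * (1 - pbar)
    X2 <- ifelse(pq > 0, (sk2 - 2 * pbar * sk + pbar^2 * sn) / pq, 0)
    nbar <- ifelse(w > 0, sn / pmax(w, 1), 0)
    r <- ifelse(w > 1 & nbar > 1, (X2 / (w - 1) - 1) / (nbar - 1), 0)
    r[!is.finite(r)] <- 0
    raw[ii] <- r
  }
  anchor <- max(0, mean(raw))
  pmax(0, 0.5 * pmax(raw, 0) + 0.5 * anchor)
}

#' Two-group beta-binomial Wald test at CpG sites
#'
#' Per site, each group's methylation level is the pooled proportion over
#' replicates; its variance under a beta-binomial model with dispersion phi
#' is \code{sum(n_i p (1-p) (1 + (n_i - 1) phi)) / (sum n_i)^2}.  The Wald
#' statistic is \code{z = (mu1 - mu2) / sqrt(var1 + var2)} with a two-sided
#' normal p-value; sites with zero difference and zero variance get z = 0,
#' p = 1.  Dispersion is estimated per group by method of moments across
#' replicates, or from neighbouring sites within \code{smooth_span} when a
#' group has a single replicate.
#'
#' @param groupA,groupB lists of \code{cpg_count_table} (>= 1 each); the
#'   reported difference is A - B.
#' @param smooth_span single-replicate dispersion window (bp; 0 disables,
#'   giving binomial variances).
#' @param phi_override optional fixed dispersion (scalar), bypassing
#'   estimation; useful for calibration work.
#' @return data.frame of class \code{dml_records}: chrom, pos, mu1, mu2,
#'   diff, phi1, phi2, stat, pval, fdr, plus per-group pooled coverages.
#' @export
dml_test <- function(groupA, groupB, smooth_span = 500L,
                     phi_override = NULL) {
  if (inherits(groupA, "cpg_count_table")) groupA <- list(groupA)
  if (inherits(groupB, "cpg_count_table")) groupB <- list(groupB)
  sa <- stack_tables(groupA)
  sb <- stack_tables(groupB)
  common <- sa$sites[sb$sites, on = c("chrom", "pos"), nomatch = NULL]
  if (nrow(common) == 0L) {
    warning("no common sites between the two groups")
    out <- data.frame(chrom = character(0), pos = integer(0),
                      mu1 = numeric(0), mu2 = numeric(0), diff = numeric(0),
                      phi1 = numeric(0), phi2 = numeric(0),
                      n1 = numeric(0), n2 = numeric(0),
                      stat = numeric(0), pval = numeric(0), fdr = numeric(0))
    class(out) <- c("dml_records", "data.frame")
    return(out)
  }
  ia <- sa$sites[common, on = c("chrom", "pos"), which = TRUE]
  ib <- sb$sites[common, on = c("chrom", "pos"), which = TRUE]
  ka <- sa$k[ia, , drop = FALSE]; na <- sa$n[ia, , drop = FALSE]
  kb <- sb$k[ib, , drop = FALSE]; nb <- sb$n[ib, , drop = FALSE]
  Na <- rowSums(na); Nb <- rowSums(nb)
  keep <- Na > 0 & Nb > 0
  common <- common[keep]; ka <- ka[keep, , drop = FALSE]
  na <- na[keep, , drop = FALSE]; kb <- kb[keep, , drop = FALSE]
  nb <- nb[keep, , drop = FALSE]; Na <- Na[keep]; Nb <- Nb[keep]
  mu1 <- rowSums(ka) / Na
  mu2 <- rowSums(kb) / Nb
  est_phi <- function(k, n, sites) {
    if (!is.null(phi_override)) return(rep(phi_override, nrow(k)))
    if (ncol(k) >= 2L) return(dispersion_mom(k, n))
    if (smooth_span > 0) return(dispersion_local(sites, k, n, smooth_span))
    rep(0, nrow(k))
  }
  phi1 <- est_phi(ka, na, common)
  phi2 <- est_phi(kb, nb, common)
  bb_var <- function(mu, phi, n, N)
    rowSums(n * (mu * (1 - mu)) * (1 + (n - 1) * phi)) / N^2
  v1 <- bb_var(mu1, phi1, na, Na)
  v2 <- bb_var(mu2, phi2, nb, Nb)
  d <- mu1 - mu2
  v <- v1 + v2
  z <- ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.infinite(z), 0, 2 * pnorm(-abs(z)))
  p[d == 0 & v == 0] <- 1
  out <- data.frame(chrom = common$chrom, pos = common$pos, mu1 = mu1,
                    mu2 = mu2, diff = d, phi1 = phi1, phi2 = phi2,
                    n1 = Na, n2 = Nb, stat = z, pval = p,
                    fdr = bh_fdr(p))
  class(out) <- c("dml_records", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' \code{p.adjust(method = "BH")}), order-preserving.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Site-level differential loci at an FDR threshold
#'
#' Thin preset over \code{\link{dml_test}} output, e.g. epiblast-specific
#' loci are sites with q < 0.05 and positive difference.
#'
#' @param records \code{dml_records}.
#' @param fdr q-value threshold.
#' @param direction "pos" (group1 > group2), "neg", or "both".
#' @return the significant subset of \code{records}.
#' @export
call_dmls <- function(records, fdr = 0.05, direction = c("pos", "neg",
                                                         "both")) {
  direction <- match.arg(direction)
  keep <- records$fdr < fdr
  if (direction == "pos") keep <- keep & records$diff > 0
  if (direction == "neg") keep <- keep & records$diff < 0
  records[keep, , drop = FALSE]
}

#' Tile-level differential methylation (DMT calling)
#'
#' Partitions each chromosome into nonoverlapping \code{tile_size} windows
#' (\code{[k*size, (k+1)*size)}), sums per-sample counts over the CpG sites
#' in each tile, keeps tiles whose pooled coverage reaches
#' \code{tile_min_cov} in every sample (and that contain at least one
#' site), runs the beta-binomial Wald test on tiles as pseudo-loci, and
#' calls a DMT where q < \code{tile_fdr} and the group1 - group2 difference
#' exceeds \code{tile_diff} (the hypomethylated-in-group2 direction).
#'
#' @param samples list of \code{cpg_count_table} (all samples).
#' @param groups character/factor of length \code{length(samples)} with
#'   exactly two levels; the first level is group1 (conventionally WT).
#' @param params \code{\link{test_params}}.
#' @return list(records, dmt): per-tile \code{dml_records} augmented with
#'   start/end/nCG, and the significant DMT subset.
#' @export
call_dmts <- function(samples, groups, params = test_params()) {
  groups <- as.character(groups)
  if (length(groups) != length(samples))
    stop("groups must label every sample")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  size <- params$tile_size
  tiled <- lapply(samples, function(s) {
    d <- data.table::as.data.table(as.data.frame(s))
    d[, tile := (pos %/% size)]
    t <- d[, .(meth = sum(meth), unmeth = sum(unmeth), nCG = .N),
           by = .(chrom, tile)]
    t
  })
  # eligibility: pooled coverage >= tile_min_cov in EVERY sample
  all_t <- data.table::rbindlist(lapply(seq_along(tiled), function(i) {
    x <- data.table::copy(tiled[[i]]); x[, samp := i]; x
  }))
  stat <- all_t[, .(n_samp = .N, min_cov = min(meth + unmeth),
                    nCG = max(nCG)), by = .(chrom, tile)]
  elig <- stat[n_samp == length(samples) & min_cov >= params$tile_min_cov]
  if (nrow(elig) == 0L)
    return(list(records = data.frame(), dmt = data.frame()))
  tile_tables <- lapply(tiled, function(t) {
    x <- t[elig[, .(chrom, tile)], on = c("chrom", "tile"), nomatch = NULL]
    cpg_count_table(data.frame(chrom = x$chrom, pos = x$tile * size,
                               meth = x$meth, unmeth = x$unmeth))
  })
  rec <- dml_test(tile_tables[groups == lev[1L]],
                  tile_tables[groups == lev[2L]],
                  smooth_span = 0L)
  rec$start <- rec$pos
  rec$end <- rec$pos + size
  rec$nCG <- elig$nCG[match(paste(rec$chrom, rec$pos %/% size),
                            paste(elig$chrom, elig$tile))]
  dmt <- rec[rec$fdr < params$tile_fdr & rec$diff > params$tile_diff, ,
             drop = FALSE]
  list(records = rec, dmt = dmt)
}

#' Region-level differential methylation (DMR calling)
#'
#' Sites with p below \code{dmr_p} seed candidate regions; maximal runs of
#' seeds at most \code{dmr_merge_gap} apart define candidates (non-seed
#' sites inside the span are included).  Candidates are kept when they hold
#' at least \code{dmr_minCG} sites, span at least \code{dmr_minlen} bp,
#' have a seed fraction of at least \code{dmr_pct_sig} and an absolute mean
#' difference of at least \code{dmr_delta}.  Adjacent same-direction
#' regions closer than the merge gap are merged.
#'
#' @param records site-level \code{dml_records}, sorted by position.
#' @param params \code{\link{test_params}}.
#' @return data.frame of class \code{dmr_set}: chrom, start, end, nCG,
#'   mean_diff, direction (WT_gt_KO = positive difference), frac_sig.
#' @export
call_dmrs <- function(records, params = test_params()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), nCG = integer(0),
                      mean_diff = numeric(0), direction = character(0),
                      frac_sig = numeric(0))
  class(empty) <- c("dmr_set", "data.frame")
  if (nrow(records) == 0L) return(empty)
  dt <- data.table::as.data.table(records)
  if (any(dt[, is.unsorted(pos), by = chrom]$V1))
    stop("contract violation: records must be sorted by position")
  out <- list()
  for (ch in unique(dt$chrom)) {
    r <- dt[chrom == ch]
    seeds <- which(r$pval < params$dmr_p)
    if (!length(seeds)) next
    spos <- r$pos[seeds]
    brk <- c(0L, cumsum(base::diff(spos) > params$dmr_merge_gap))
    for (b in unique(brk)) {
      sp <- spos[brk == b]
      start <- sp[1L]
      end <- sp[length(sp)] + 2L       # cover the final CpG dinucleotide
      inside <- r[pos >= start & pos < end]
      nCG <- nrow(inside)
      frac <- length(sp) / nCG
      md <- mean(inside$diff)
      if (nCG >= params$dmr_minCG && (end - start) >= params$dmr_minlen &&
          frac >= params$dmr_pct_sig && abs(md) >= params$dmr_delta) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = start, end = end, nCG = nCG, mean_diff = md,
          direction = if (md > 0) "WT_gt_KO" else "KO_gt_WT",
          frac_sig = frac, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  # merge adjacent same-direction regions
  merged <- list()
  cur <- res[1L, ]
  if (nrow(res) > 1L) for (i in 2:nrow(res)) {
    nxt <- res[i, ]
    if (nxt$chrom == cur$chrom && nxt$direction == cur$direction &&
        nxt$start - cur$end <= params$dmr_merge_gap) {
      w <- c(cur$nCG, nxt$nCG)
      cur$mean_diff <- sum(w * c(cur$mean_diff, nxt$mean_diff)) / sum(w)
      cur$frac_sig <- sum(w * c(cur$frac_sig, nxt$frac_sig)) / sum(w)
      cur$end <- nxt$end
      cur$nCG <- sum(w)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1L]] <- cur
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  class(res) <- c("dmr_set", "data.frame")
  res
}

#' Methylation-level category fractions
#'
#' Splits retained sites into hypermethylated (level > 0.8), intermediate
#' (0.2 <= level <= 0.8) and hypomethylated (level < 0.2) fractions.
#'
#' @param table a coverage-filtered \code{cpg_count_table}.
#' @return named numeric vector (hyper, intermediate, hypo) summing to 1.
#' @export
methylation_categories <- function(table) {
  lvl <- meth_level(table)
  lvl <- lvl[!is.na(lvl)]
  if (length(lvl) == 0L)
    stop("category fractions are undefined on an empty table")
  c(hyper = mean(lvl > 0.8),
    intermediate = mean(lvl >= 0.2 & lvl <= 0.8),
    hypo = mean(lvl < 0.2))
}

#' Per-chromosome methylation log2 fold change
#'
#' For each chromosome, computes the mean level over sites shared by the
#' two (coverage-filtered) tables and reports log2(mean_KO / mean_WT).
#'
#' @param ko,wt \code{cpg_count_table}s (filtered, e.g. >= 5x).
#' @param min_sites minimal shared sites per chromosome.
#' @return data.frame chrom, log2fc, n_sites (log2fc NA when the chromosome
#'   has too few shared sites or a zero wild-type mean).
#' @export
chromosome_log2fc <- function(ko, wt, min_sites = 100L) {
  a <- data.table::as.data.table(as.data.frame(ko))
  b <- data.table::as.data.table(as.data.frame(wt))
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_ko", "_wt"))
  m[, `:=`(lko = meth_ko / (meth_ko + unmeth_ko),
           lwt = meth_wt / (meth_wt + unmeth_wt))]
  res <- m[, .(mko = mean(lko), mwt = mean(lwt), n_sites = .N), by = chrom]
  res[, log2fc := ifelse(n_sites >= min_sites & mwt > 0,
                         log2(mko / mwt), NA_real_)]
  if (any(is.na(res$log2fc)))
    msg("chromosome(s) reported as missing: ",
        paste(res$chrom[is.na(res$log2fc)], collapse = ", "))
  as.data.frame(res[, .(chrom, log2fc, n_sites)])
}

#' Export DMT/DMR calls as BED
#'
#' 0-based half-open intervals; name = direction, score = -10 log10(p)
#' capped at 1000 (regions without a single p use the capped maximum).
#'
#' @param regions data.frame with chrom/start/end and optionally
#'   direction/pval.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  score <- if (!is.null(regions$pval))
    pmin(1000, round(-10 * log10(pmax(regions$pval, 1e-100)))) else
      rep(1000L, nrow(regions))
  name <- regions$direction %||% rep(".", nrow(regions))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", regions$chrom, regions$start,
                   regions$end, name, as.integer(score))
  writeLines(lines, path)
  invisible(path)
}
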