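# per-CpG methylation extraction, aggregation and coverage-file I/O

#' Read-end trim windows for methylation extraction
#'
#' Defaults reproduce the standard paired-end extraction trims: the first
#' 10 bases and the last 5 bases of each mate are ignored (M-bias guard).
#'
#' @param ignore_5prime_r1,ignore_5prime_r2 bases ignored at each mate's 5'
#'   end.
#' @param ignore_3prime_r1,ignore_3prime_r2 bases ignored at each mate's 3'
#'   end.
#' @return list of class \code{trim_windows}.
#' @export
trim_windows <- function(ignore_5prime_r1 = 10L, ignore_5prime_r2 = 10L,
                         ignore_3prime_r1 = 5L, ignore_3prime_r2 = 5L) {
  w <- list(ignore_5prime_r1 = ignore_5prime_r1,
            ignore_5prime_r2 = ignore_5prime_r2,
            ignore_3prime_r1 = ignore_3prime_r1,
            ignore_3prime_r2 = ignore_3prime_r2)
  if (any(unlist(w) < 0L)) stop("trim windows must be >= 0")
  class(w) <- "trim_windows"
  w
}

#' Extract per-CpG methylation calls from aligned pairs
#'
#' For every reference CpG covered on a pair's informative strand
#' (plus-strand C for OT/CTOT fragments; the G of the dinucleotide, mapped
#' back to the site's C coordinate, for OB/CTOB), an observed C (or G on
#' the bottom strand) is a methylated call and T (or A) an unmethylated
#' call; any other base gives no call.  Bases inside the trim windows give
#' no call; CpG sites destroyed or created by a SNP in either genome give
#' no call; bases seen by both mates are counted once (mate 1 wins).
#'
#' @param pairs mapped \code{aligned_pairs}.
#' @param genome the \code{ref_genome} the pairs are mapped to.
#' @param trim \code{\link{trim_windows}}.
#' @param exclude optional data.frame (chrom, pos) of CpG sites to skip,
#'   e.g. \code{\link{snp_destroyed_cpgs}} output.
#' @param cpg optional precomputed \code{\link{index_cpg_sites}} result.
#' @return data.table of class \code{methylation_calls}: chrom, pos (site C
#'   coordinate), meth (logical), strand (evidence strand), id, frag_key.
#' @export
call_methylation <- function(pairs, genome, trim = trim_windows(),
                             exclude = NULL, cpg = NULL) {
  pairs <- data.table::as.data.table(pairs)
  pairs <- pairs[mapped == TRUE]
  if (is.null(cpg)) cpg <- index_cpg_sites(genome)
  out <- list()
  for (mate in 1:2) {
    st <- if (mate == 1L) pairs$start1 else pairs$start2
    or <- if (mate == 1L) pairs$orient1 else pairs$orient2
    sq <- if (mate == 1L) pairs$seq1 else pairs$seq2
    L <- pairs$read_len
    t5 <- if (mate == 1L) trim$ignore_5prime_r1 else trim$ignore_5prime_r2
    t3 <- if (mate == 1L) trim$ignore_3prime_r1 else trim$ignore_3prime_r2
    if (any(t5 + t3 >= L)) {
      msg("trim windows leave no usable bases on mate ", mate)
      next
    }
    top_strand <- pairs$strand %in% c("OT", "CTOT")
    # genomic coordinate carrying the evidence base
    rows <- list()
    for (ch in unique(pairs$chrom)) {
      S <- cpg[[ch]]
      if (is.null(S) || length(S) == 0L) next
      ii <- which(pairs$chrom == ch)
      # evidence position: site C for top-strand reads, site+1 for bottom
      ev_off <- ifelse(top_strand[ii], 0L, 1L)
      lo <- findInterval(st[ii] - 1L + ifelse(top_strand[ii], 0L, -1L), S) + 1L
      hi <- findInterval(st[ii] + L[ii] - 1L - ev_off, S)
      nn <- pmax(0L, hi - lo + 1L)
      keep <- nn > 0L
      if (!any(keep)) next
      idx <- sequence(nn[keep]) + rep(lo[keep] - 1L, nn[keep])
      rr <- data.table::data.table(
        pi = rep(ii[keep], nn[keep]), chrom = ch, pos = S[idx])
      rows[[ch]] <- rr
    }
    if (!length(rows)) next
    rr <- data.table::rbindlist(rows)
    rr[, top := top_strand[pi]]
    rr[, ev := pos + ifelse(top, 0L, 1L)]
    rr <- rr[ev >= st[pi] & ev < st[pi] + L[pi]]
    if (nrow(rr) == 0L) next
    rr[, i_read := ifelse(or[pi] == "F", ev - st[pi],
                          (st[pi] + L[pi] - 1L) - ev)]
    rr <- rr[i_read >= t5 & i_read < L[pi] - t3]
    if (nrow(rr) == 0L) next
    rr[, obs_raw := substr(sq[pi], i_read + 1L, i_read + 1L)]
    rr[, obs := ifelse(or[pi] == "F", obs_raw, comp_base(obs_raw))]
    # top-strand terms: C/T at the site C; G/A at the site G
    rr[, call := data.table::fcase(
      top & obs == "C", TRUE, top & obs == "T", FALSE,
      !top & obs == "G", TRUE, !top & obs == "A", FALSE,
      default = NA)]
    rr <- rr[!is.na(call)]
    if (nrow(rr) == 0L) next
    rr[, `:=`(mate = mate, id = pairs$id[pi],
              strand = pairs$strand[pi],
              frag_key = paste0(pairs$chrom[pi], ":",
                                pmin(pairs$start1[pi], pairs$start2[pi]),
                                "-",
                                pmax(pairs$start1[pi], pairs$start2[pi]) +
                                  L[pi], ":", pairs$strand[pi]))]
    out[[mate]] <- rr[, .(chrom, pos, meth = call, strand, id, mate,
                          frag_key)]
  }
  if (!length(out)) {
    calls <- data.table::data.table(chrom = character(0), pos = integer(0),
                                    meth = logical(0), strand = character(0),
                                    id = character(0), mate = integer(0),
                                    frag_key = character(0))
  } else {
    calls <- data.table::rbindlist(out)
    data.table::setorder(calls, chrom, pos, id, mate)
    calls <- calls[!duplicated(calls[, .(id, pos, chrom)])]
  }
  if (!is.null(exclude) && nrow(exclude) && nrow(calls)) {
    ex <- data.table::as.data.table(exclude[, c("chrom", "pos")])
    calls <- calls[!ex, on = c("chrom", "pos")]
  }
  data.table::setattr(calls, "class",
                      c("methylation_calls", class(data.table::data.table())))
  calls
}

#' Per-CpG count table
#'
#' @param df data.frame with chrom, pos (0-based plus-strand C coordinate),
#'   meth, unmeth counts.
#' @param sample sample label.
#' @return data.frame of class \code{cpg_count_table}; the derived
#'   methylation level is \code{meth / (meth + unmeth)} where coverage > 0.
#' @export
cpg_count_table <- function(df, sample = "sample") {
  stopifnot(all(c("chrom", "pos", "meth", "unmeth") %in% names(df)))
  if (any(df$meth < 0 | df$unmeth < 0)) stop("counts must be >= 0")
  df <- df[order(df$chrom, df$pos), c("chrom", "pos", "meth", "unmeth")]
  rownames(df) <- NULL
  attr(df, "sample") <- sample
  class(df) <- c("cpg_count_table", "data.frame")
  df
}

#' @export
print.cpg_count_table <- function(x, ...) {
  cov <- x$meth + x$unmeth
  cat("cpg_count_table '", attr(x, "sample"), "': ", nrow(x),
      " sites, mean coverage ", round(mean(cov), 2), "\n", sep = "")
  invisible(x)
}

# methylation level vector of a count table
meth_level <- function(table) {
  cov <- table$meth + table$unmeth
  ifelse(cov > 0, table$meth / cov, NA_real_)
}

#' Aggregate methylation calls into a per-site count table
#'
#' Plus- and minus-strand evidence for one CpG dinucleotide is merged into
#' one record at the plus-strand C coordinate.  With \code{dedup},
#' fragments sharing (chrom, start, end, strand) contribute once.
#'
#' @param calls a \code{methylation_calls} table.
#' @param dedup drop duplicate fragments (default TRUE, the whole-genome
#'   convention; capture libraries are aggregated with \code{dedup =
#'   FALSE}).
#' @param sample sample label.
#' @return a \code{\link{cpg_count_table}}.
#' @export
aggregate_counts <- function(calls, dedup = TRUE, sample = "sample") {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) && dedup) {
    rep_id <- calls[, .(rep = min(id)), by = frag_key]
    calls <- calls[rep_id, on = c("frag_key", id = "rep")]
  }
  if (nrow(calls) == 0L)
    return(cpg_count_table(data.frame(chrom = character(0), pos = integer(0),
                                      meth = integer(0), unmeth = integer(0)),
                           sample))
  tab <- calls[, .(meth = sum(meth), unmeth = sum(!meth)),
               by = .(chrom, pos)]
  cpg_count_table(as.data.frame(tab), sample)
}

#' Coverage filter
#'
#' Keeps sites with coverage at least \code{min_cov}.  Conventional values:
#' 5 for visualization and summaries, 10 for tiles (pooled), 50 for
#' capture-mode region calling (pooled).
#'
#' @param table a \code{cpg_count_table}.
#' @param min_cov minimal coverage (>= 1).
#' @return filtered \code{cpg_count_table}.
#' @export
filter_table <- function(table, min_cov) {
  if (min_cov < 1) stop("min_cov must be >= 1")
  keep <- (table$meth + table$unmeth) >= min_cov
  cpg_count_table(as.data.frame(table)[keep, , drop = FALSE],
                  attr(table, "sample"))
}

#' Restrict evidence to one original strand
#'
#' \code{original_bottom_only} keeps OB/CTOB-derived evidence only,
#' emulating capture designs whose probes target the original top strand
#' (so only bottom-strand reads are informative); \code{both} is the
#' default identity.
#'
#' @param calls a \code{methylation_calls} table (or any table with a
#'   \code{strand} column).
#' @param mode "both" or "original_bottom_only".
#' @return filtered table.
#' @export
strand_restrict <- function(calls, mode = c("both", "original_bottom_only")) {
  mode <- match.arg(mode)
  if (mode == "both") return(calls)
  out <- calls[calls$strand %in% c("OB", "CTOB"), ]
  out
}

#' Coverage-file I/O
#'
#' Standard six-column coverage format:
#' \code{chrom<TAB>start1<TAB>end1<TAB>meth_percent<TAB>count_meth<TAB>count_unmeth}
#' with 1-based inclusive coordinates and the percentage printed with one
#' decimal.  On read, counts are authoritative: a missing or inconsistent
#' percentage is recomputed (with a warning in the inconsistent case).
#'
#' @param table a \code{cpg_count_table}.
#' @param path file path.
#' @export
write_coverage <- function(table, path) {
  cov <- table$meth + table$unmeth
  pct <- ifelse(cov > 0, 100 * table$meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%.1f\t%d\t%d", table$chrom, table$pos + 1L,
                   table$pos + 1L, pct, table$meth, table$unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' @param sample sample label for the table read back.
#' @rdname write_coverage
#' @export
read_coverage <- function(path, sample = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5L))
    stop("malformed coverage row at line ", which(nf < 5L)[1L])
  get <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else NA_character_, "")
  chrom <- get(1L)
  start1 <- suppressWarnings(as.integer(get(2L)))
  has_pct <- nf >= 6L
  pct <- suppressWarnings(as.numeric(ifelse(has_pct, get(4L), NA)))
  meth <- suppressWarnings(as.integer(ifelse(has_pct, get(5L), get(4L))))
  unmeth <- suppressWarnings(as.integer(ifelse(has_pct, get(6L), get(5L))))
  bad <- is.na(start1) | is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0
  if (any(bad)) stop("malformed coverage row at line ", which(bad)[1L])
  cov <- meth + unmeth
  true_pct <- ifelse(cov > 0, 100 * meth / cov, 0)
  off <- has_pct & !is.na(pct) & abs(pct - true_pct) > 0.05 + 1e-9
  if (any(off))
    warning(sum(off), " row(s) had inconsistent methylation percentage; ",
            "recomputed from counts")
  cpg_count_table(data.frame(chrom = chrom, pos = start1 - 1L, meth = meth,
                             unmeth = unmeth), sample)
}

#' Merge count tables site-wise
#'
#' Sums methylated/unmethylated counts over tables (e.g. pooling alleles or
#' replicates).
#' @param tables list of \code{cpg_count_table}.
#' @param sample label of the merged table.
#' @return a \code{cpg_count_table}.
#' @export
merge_count_tables <- function(tables, sample = "pooled") {
  dt <- data.table::rbindlist(lapply(tables, as.data.frame))
  tab <- dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
  cpg_count_table(as.data.frame(tab), sample)
}
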