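# dual-genome concordance and conversion-aware allele assignment

#' Dual-genome mapping concordance filter
#'
#' A read pair enters allele-specific analysis only when it maps uniquely
#' to both haplotype genomes, on the same chromosome, at identical leftmost
#' positions (substitution-only genomes guarantee coordinate identity) and
#' with the same origin strand; every other pair is discordant.
#'
#' @param aln_g1,aln_g2 \code{aligned_pairs} tables for the same read set
#'   against genome1 and genome2.
#' @return the genome1-coordinate \code{aligned_pairs} rows of concordant
#'   pairs, with a \code{concordant} flag added to a copy of the full input
#'   in \code{attr(, "status")} (id, concordant).
#' @export
dual_map_concordance <- function(aln_g1, aln_g2) {
  a1 <- data.table::as.data.table(aln_g1)
  a2 <- data.table::as.data.table(aln_g2)
  m <- merge(a1[, .(id, chrom, start1, start2, strand, mapped, unique)],
             a2[, .(id, chrom, start1, start2, strand, mapped, unique)],
             by = "id", suffixes = c("_1", "_2"))
  ok <- m$mapped_1 & m$mapped_2 & m$unique_1 & m$unique_2 &
    m$chrom_1 == m$chrom_2 & m$start1_1 == m$start1_2 &
    m$start2_1 == m$start2_2 & m$strand_1 == m$strand_2
  ok[is.na(ok)] <- FALSE
  keep_ids <- m$id[ok]
  out <- a1[id %in% keep_ids]
  data.table::setattr(out, "class", class(aln_g1))
  attr(out, "status") <- data.frame(id = m$id, concordant = ok)
  out
}

#' Assign read pairs to parental alleles
#'
#' For every informative SNP overlapped by either mate of a concordant
#' pair, the observed base votes for the allele it matches exactly.  A SNP
#' is skipped when it lies in a CpG dinucleotide, when it is
#' conversion-blocked for the pair's origin strand (\{C,T\} SNPs on
#' OT/CTOT reads, \{G,A\} on OB/CTOB), when the base falls inside the
#' ignored read ends, when its base quality is below \code{min_base_qual},
#' or when the observed base matches neither allele.  Bases seen by both
#' mates are examined once (mate 1 wins).  Under the strict policy a pair
#' is assigned only when all votes agree; any split vote is a conflict.
#' Under the majority policy the winning allele needs at least
#' \code{majority_frac} of at least two votes.
#'
#' @param pairs concordant \code{aligned_pairs} (genome1 coordinates).
#' @param snps informativeness-annotated \code{snp_table}.
#' @param policy "strict" or "majority".
#' @param majority_frac winning-vote fraction for the majority policy.
#' @param min_base_qual Phred floor for a base to vote.
#' @param trim \code{\link{trim_windows}} applied to voting positions (the
#'   methylation-extraction trims are reused here as a conservative
#'   extension; the original analysis trimmed only methylation calls).
#' @param keep_votes return the per-SNP vote log in \code{attr(, "votes")}.
#' @return data.frame of class \code{allelic_assignment}: id, verdict
#'   (genome1/genome2/unassigned/conflict), n_snps, votes_g1, votes_g2,
#'   n_skipped.
#' @export
assign_alleles <- function(pairs, snps, policy = c("strict", "majority"),
                           majority_frac = 2 / 3, min_base_qual = 20L,
                           trim = trim_windows(), keep_votes = FALSE) {
  policy <- match.arg(policy)
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) && anyNA(pairs$strand))
    stop("contract violation: aligned pair without origin strand")
  sn <- data.table::as.data.table(as.data.frame(snps))
  votes <- list()
  for (mate in 1:2) {
    st <- if (mate == 1L) pairs$start1 else pairs$start2
    or <- if (mate == 1L) pairs$orient1 else pairs$orient2
    L <- pairs$read_len
    rd <- data.table::data.table(row = seq_len(nrow(pairs)),
                                 chrom = pairs$chrom, start = st,
                                 end = st + L, orient = or)
    ov <- sn[rd, on = .(chrom, pos >= start, pos < end), nomatch = NULL,
             .(row = i.row, chrom, snp_pos = x.pos, allele1 = x.allele1,
               allele2 = x.allele2, in_cpg = x.in_cpg,
               informative_ot = x.informative_ot,
               informative_ob = x.informative_ob)]
    if (nrow(ov) == 0L) next
    ov[, `:=`(mate = mate,
              start = st[row], orient = or[row],
              strand = pairs$strand[row], id = pairs$id[row],
              seq = if (mate == 1L) pairs$seq1[row] else pairs$seq2[row],
              qual = if (mate == 1L) pairs$qual1[row] else pairs$qual2[row],
              L = L[row])]
    votes[[mate]] <- ov
  }
  base <- data.frame(id = pairs$id, verdict = rep("unassigned", nrow(pairs)),
                     n_snps = 0L, votes_g1 = 0L, votes_g2 = 0L,
                     n_skipped = 0L, stringsAsFactors = FALSE)
  if (!length(votes)) {
    class(base) <- c("allelic_assignment", "data.frame")
    return(base)
  }
  v <- data.table::rbindlist(votes)
  # one look per molecule position: mate 1's copy wins in the overlap
  data.table::setorder(v, id, snp_pos, mate)
  v <- v[!duplicated(v[, .(id, snp_pos)])]
  # read coordinate of the SNP base
  v[, i_read := ifelse(orient == "F", snp_pos - start,
                       (start + L - 1L) - snp_pos)]
  t5 <- ifelse(v$mate == 1L, trim$ignore_5prime_r1, trim$ignore_5prime_r2)
  t3 <- ifelse(v$mate == 1L, trim$ignore_3prime_r1, trim$ignore_3prime_r2)
  v[, in_trim := i_read < t5 | i_read >= (L - t3)]
  # observed base in top-strand terms
  v[, obs_raw := substr(seq, i_read + 1L, i_read + 1L)]
  v[, obs := ifelse(orient == "F", obs_raw, comp_base(obs_raw))]
  v[, q := utf8ToInt_vec(qual, i_read + 1L) - 33L]
  top_strand <- v$strand %in% c("OT", "CTOT")
  v[, informative := ifelse(top_strand, informative_ot, informative_ob)]
  v[, reason := data.table::fcase(
    in_cpg, "cpg",
    !informative, "conversion_blocked",
    in_trim, "trimmed_end",
    q < min_base_qual, "low_quality",
    obs == allele1, "vote_g1",
    obs == allele2, "vote_g2",
    default = "base_mismatch")]
  tallies <- v[, .(n_snps = .N,
                   votes_g1 = sum(reason == "vote_g1"),
                   votes_g2 = sum(reason == "vote_g2"),
                   n_skipped = sum(!reason %in% c("vote_g1", "vote_g2"))),
               by = id]
  i <- match(tallies$id, base$id)
  base$n_snps[i] <- tallies$n_snps
  base$votes_g1[i] <- tallies$votes_g1
  base$votes_g2[i] <- tallies$votes_g2
  base$n_skipped[i] <- tallies$n_skipped
  g1 <- base$votes_g1; g2 <- base$votes_g2
  if (policy == "strict") {
    base$verdict[g1 > 0L & g2 == 0L] <- "genome1"
    base$verdict[g2 > 0L & g1 == 0L] <- "genome2"
    base$verdict[g1 > 0L & g2 > 0L] <- "conflict"
  } else {
    tot <- g1 + g2
    win1 <- tot >= 2L & g1 / pmax(tot, 1L) >= majority_frac
    win2 <- tot >= 2L & g2 / pmax(tot, 1L) >= majority_frac
    base$verdict[win1] <- "genome1"
    base$verdict[win2] <- "genome2"
    base$verdict[!win1 & !win2 & g1 > 0L & g2 > 0L] <- "conflict"
  }
  class(base) <- c("allelic_assignment", "data.frame")
  if (keep_votes)
    attr(base, "votes") <- as.data.frame(
      v[, .(id, chrom, snp_pos, mate, strand, obs, reason)])
  base
}

# Phred integer of the character at position i (vectorised, per string)
utf8ToInt_vec <- function(qual, i) {
  vapply(substr(qual, i, i), function(ch)
    if (nchar(ch)) utf8ToInt(ch) else 0L, 0L, USE.NAMES = FALSE)
}

#' Export an allele assignment table as TSV
#' @param assignment an \code{allelic_assignment}.
#' @param path output file.
#' @export
write_assignments <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
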