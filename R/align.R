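# three-letter bisulfite alignment for toy genomes, plus SAM interop

#' Build a conversion-aware alignment index
#'
#' Produces two reduced-alphabet views per chromosome (C-to-T for
#' original-top searches, G-to-A for original-bottom searches) and an exact
#' k-mer seed index over both.  Intended for toy genomes up to a few
#' megabases; larger inputs should come in as external SAM alignments.
#'
#' @param genome a \code{ref_genome}.
#' @param k seed length (default 20).
#' @return object of class \code{bs_index}.
#' @export
build_converted_index <- function(genome, k = 20L) {
  if (sum(as.numeric(genome$length)) > 2e7)
    warning("internal aligner is intended for genomes <= ~10 Mb; ",
            "use external SAM alignments for larger inputs")
  keep <- genome$length >= k
  if (any(!keep))
    warning("chromosome(s) shorter than k skipped: ",
            paste(names(genome$seq)[!keep], collapse = ", "))
  seqs <- genome$seq[keep]
  views <- list(CT = vapply(seqs, ct_convert, ""),
                GA = vapply(seqs, ga_convert, ""))
  idx <- list()
  for (v in names(views)) for (ch in names(seqs)) {
    s <- views[[v]][[ch]]
    n <- nchar(s) - k + 1L
    idx[[paste(v, ch)]] <- data.table::data.table(
      view = v, kmer = substring(s, 1:n, k:(n + k - 1L)),
      chrom = ch, pos = 0:(n - 1L))
  }
  idx <- data.table::rbindlist(idx)
  data.table::setkeyv(idx, c("view", "kmer"))
  structure(list(views = views, index = idx, k = k,
                 chrom_len = genome$length[keep]),
            class = "bs_index")
}

# seed lookup: candidate leftmost positions for a set of queries
seed_candidates <- function(queries, view, index, offsets, L) {
  k <- index$k
  offsets <- offsets[offsets + k <= L]
  cand <- list()
  for (off in offsets) {
    km <- substr(queries, off + 1L, off + k)
    q <- data.table::data.table(view = view, kmer = km,
                                qid = seq_along(queries))
    hits <- index$index[q, on = c("view", "kmer"), nomatch = NULL,
                        allow.cartesian = TRUE]
    if (nrow(hits))
      cand[[length(cand) + 1L]] <-
        data.table::data.table(qid = hits$qid, chrom = hits$chrom,
                               pos = hits$pos - off)
  }
  if (!length(cand))
    return(data.table::data.table(qid = integer(0), chrom = character(0),
                                  pos = integer(0)))
  out <- unique(data.table::rbindlist(cand))
  out <- out[pos >= 0L & pos + L <= index$chrom_len[chrom]]
  out
}

# mismatch count of queries against a converted genome view
view_mismatches <- function(cand, queries, view, index, L) {
  if (nrow(cand) == 0L) return(integer(0))
  ref <- character(nrow(cand))
  for (ch in unique(cand$chrom)) {
    ii <- which(cand$chrom == ch)
    ref[ii] <- substring(index$views[[view]][[ch]],
                         cand$pos[ii] + 1L, cand$pos[ii] + L)
  }
  hamming(queries[cand$qid], ref)
}

#' Align bisulfite read pairs to a converted index
#'
#' Ungapped, match-only three-letter alignment.  Each pair is evaluated
#' under the original-top and original-bottom hypotheses (plus their
#' complementary CTOT/CTOB forms when \code{allow_complementary} is TRUE):
#' reads are converted to the reduced alphabet, candidate loci come from
#' exact k-mer seeds, candidates are extended by Hamming distance, and
#' mates must map concordantly within \code{max_fragment}.  A pair is kept
#' only when its best combined mismatch count is at most
#' \code{max_mismatches} per mate and strictly better than the second-best
#' concordant placement (unique-best rule; ties are unmapped).  Alignment
#' is invariant to methylation state by construction of the converted
#' alphabet.
#'
#' @param reads data.frame/data.table with columns id, seq1, seq2 (and
#'   optionally qual1/qual2, carried through).
#' @param index a \code{\link{build_converted_index}} result.
#' @param max_mismatches maximum mismatches per mate (default 4, tuned for
#'   100-bp reads carrying SNPs plus occasional failed conversion).
#' @param max_fragment maximal allowed fragment span in bp.
#' @param seed_offsets read offsets at which seed k-mers are taken.
#' @param allow_complementary also search CTOT/CTOB geometries.
#' @return data.table of class \code{aligned_pairs}: one row per input pair
#'   with chrom, start1/start2 (0-based leftmost position per mate),
#'   orient1/orient2 ("F"/"R"), strand (OT/OB/CTOT/CTOB), mm1/mm2, mapped
#'   flag, read length and the read sequences/qualities.
#' @export
align_read_pairs <- function(reads, index, max_mismatches = 4L,
                             max_fragment = 600L,
                             seed_offsets = c(0L, 40L, 78L),
                             allow_complementary = FALSE) {
  reads <- data.table::as.data.table(reads)
  n <- nrow(reads)
  L <- if (n) nchar(reads$seq1[1L]) else 0L
  hyps <- list(
    OT   = list(view = "CT", q1 = ct_convert(reads$seq1),
                q2 = ct_convert(revcomp(reads$seq2)), r1_rev = FALSE),
    OB   = list(view = "GA", q1 = ga_convert(revcomp(reads$seq1)),
                q2 = ga_convert(reads$seq2), r1_rev = TRUE))
  if (allow_complementary) {
    hyps$CTOT <- list(view = "CT", q1 = ct_convert(revcomp(reads$seq1)),
                      q2 = ct_convert(reads$seq2), r1_rev = TRUE)
    hyps$CTOB <- list(view = "GA", q1 = ga_convert(reads$seq1),
                      q2 = ga_convert(revcomp(reads$seq2)), r1_rev = FALSE)
  }
  all_pairs <- list()
  for (h in names(hyps)) {
    hy <- hyps[[h]]
    c1 <- seed_candidates(hy$q1, hy$view, index, seed_offsets, L)
    c2 <- seed_candidates(hy$q2, hy$view, index, seed_offsets, L)
    if (nrow(c1) == 0L || nrow(c2) == 0L) next
    c1[, mm := view_mismatches(c1, hy$q1, hy$view, index, L)]
    c2[, mm := view_mismatches(c2, hy$q2, hy$view, index, L)]
    c1 <- c1[mm <= max_mismatches]
    c2 <- c2[mm <= max_mismatches]
    if (nrow(c1) == 0L || nrow(c2) == 0L) next
    j <- merge(c1, c2, by = c("qid", "chrom"), allow.cartesian = TRUE,
               suffixes = c("1", "2"))
    if (nrow(j) == 0L) next
    # geometry: the reverse-oriented mate sits at the fragment's right edge
    left <- pmin(j$pos1, j$pos2)
    right <- pmax(j$pos1, j$pos2)
    rev_is_1 <- hy$r1_rev
    ok <- (j$pos2 >= j$pos1) == !rev_is_1 | j$pos1 == j$pos2
    frag <- right + L - left
    j <- j[ok & frag <= max_fragment]
    if (nrow(j) == 0L) next
    j[, `:=`(strand = h, score = mm1 + mm2)]
    all_pairs[[h]] <- j
  }
  out <- data.table::data.table(
    id = reads$id, chrom = NA_character_, start1 = NA_integer_,
    start2 = NA_integer_, orient1 = NA_character_,
    orient2 = NA_character_, strand = NA_character_,
    mm1 = NA_integer_, mm2 = NA_integer_, mapped = FALSE,
    unique = FALSE, read_len = L,
    seq1 = reads$seq1, seq2 = reads$seq2,
    qual1 = if ("qual1" %in% names(reads)) reads$qual1 else
      strrep("I", L),
    qual2 = if ("qual2" %in% names(reads)) reads$qual2 else
      strrep("I", L),
    source = "internal")
  if (length(all_pairs)) {
    cand <- data.table::rbindlist(all_pairs, fill = TRUE)
    data.table::setorder(cand, qid, score)
    best <- cand[, .(chrom = chrom[1L], pos1 = pos1[1L], pos2 = pos2[1L],
                     strand = strand[1L], mm1 = mm1[1L], mm2 = mm2[1L],
                     n_cand = .N,
                     second = if (.N > 1L) score[2L] else NA_integer_,
                     score = score[1L]),
                 by = qid]
    uniq <- is.na(best$second) | best$score < best$second
    best <- best[uniq]
    if (nrow(best)) {
      i <- best$qid
      rev1 <- best$strand %in% c("OB", "CTOT")
      data.table::set(out, i = i, j = "chrom", value = best$chrom)
      data.table::set(out, i = i, j = "start1", value = best$pos1)
      data.table::set(out, i = i, j = "start2", value = best$pos2)
      data.table::set(out, i = i, j = "orient1",
                      value = ifelse(rev1, "R", "F"))
      data.table::set(out, i = i, j = "orient2",
                      value = ifelse(rev1, "F", "R"))
      data.table::set(out, i = i, j = "strand", value = best$strand)
      data.table::set(out, i = i, j = "mm1", value = best$mm1)
      data.table::set(out, i = i, j = "mm2", value = best$mm2)
      data.table::set(out, i = i, j = "mapped", value = TRUE)
      data.table::set(out, i = i, j = "unique", value = TRUE)
    }
  }
  data.table::setattr(out, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  out
}

# bisulfite strand from the conventional tag pair (genome conversion XG,
# read conversion XR)
strand_from_tags <- function(xg, xr) {
  key <- paste(xg, xr)
  map <- c("CT CT" = "OT", "CT GA" = "CTOT", "GA CT" = "OB",
           "GA GA" = "CTOB")
  unname(map[key])
}

#' Read external bisulfite alignments from SAM
#'
#' Ingests paired alignments produced by an external bisulfite aligner.
#' The origin strand is taken from the conventional bisulfite tags (XG =
#' genome conversion CT/GA crossed with XR = read conversion) when present,
#' and otherwise inferred from FLAG orientation under the directional
#' protocol assumption (with a warning).  Records with MAPQ below
#' \code{min_mapq} are dropped.
#'
#' @param path SAM file (with header).
#' @param genome \code{ref_genome} the alignments refer to.
#' @param min_mapq MAPQ threshold (default 20).
#' @return an \code{aligned_pairs} table (source = "external").
#' @export
read_sam <- function(path, genome, min_mapq = 20L) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq", "cigar"),
    tag = c("XG", "XR"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  dt <- data.table::data.table(
    qname = b$qname, flag = b$flag, chrom = as.character(b$rname),
    pos = b$pos - 1L, mapq = b$mapq, seq = as.character(b$seq),
    xg = b$tag$XG %||% rep(NA_character_, length(b$qname)),
    xr = b$tag$XR %||% rep(NA_character_, length(b$qname)))
  dt <- dt[!is.na(pos)]
  if (nrow(dt) && !all(dt$chrom %in% names(genome$seq)))
    stop("SAM records on chromosome absent from the genome: ",
         setdiff(dt$chrom, names(genome$seq))[1L])
  dt <- dt[is.na(mapq) | mapq >= min_mapq]
  dt[, `:=`(first = bitwAnd(flag, 64L) > 0L,
            rev = bitwAnd(flag, 16L) > 0L)]
  # XR describes the mate's own conversion; the fragment strand is defined
  # by mate 1's pair, so flip XR for mate 2 before mapping
  dt[, xr_eff := ifelse(first | is.na(xr), xr,
                        ifelse(xr == "CT", "GA", "CT"))]
  dt[, strand := strand_from_tags(xg, xr_eff)]
  noinf <- is.na(dt$strand)
  if (any(noinf)) {
    warning("bisulfite tags missing for ", sum(noinf),
            " record(s); inferring strand from FLAG orientation ",
            "(directional protocol assumed)")
    # directional: first mate forward => OT fragment, first mate reverse => OB
    dt[noinf & first, strand := ifelse(rev, "OB", "OT")]
    dt[noinf & !first, strand := ifelse(rev, "OT", "OB")]
  }
  # SAM stores reverse-strand SEQ in genome orientation; restore read
  # orientation to match the internal convention
  dt[rev == TRUE, seq := revcomp(seq)]
  m1 <- dt[first == TRUE]
  m2 <- dt[first == FALSE]
  j <- merge(m1, m2, by = "qname", suffixes = c("1", "2"))
  j <- j[chrom1 == chrom2 & strand1 == strand2]
  L <- if (nrow(j)) nchar(j$seq1[1L]) else 0L
  out <- data.table::data.table(
    id = j$qname, chrom = j$chrom1, start1 = j$pos1, start2 = j$pos2,
    orient1 = ifelse(j$rev1, "R", "F"), orient2 = ifelse(j$rev2, "R", "F"),
    strand = j$strand1, mm1 = NA_integer_, mm2 = NA_integer_,
    mapped = TRUE, unique = TRUE, read_len = nchar(j$seq1),
    seq1 = j$seq1, seq2 = j$seq2,
    qual1 = strrep("I", nchar(j$seq1)), qual2 = strrep("I", nchar(j$seq2)),
    source = "external")
  data.table::setattr(out, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  out
}

#' Write internal alignments as SAM
#'
#' Minimal SAM with @HD/@SQ header, FLAG, 1-based POS, all-match CIGAR and
#' the conventional bisulfite tags (XG genome conversion, XR read
#' conversion).
#'
#' @param aligned an \code{aligned_pairs} table.
#' @param genome the \code{ref_genome} aligned against.
#' @param path output path.
#' @export
write_sam <- function(aligned, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq),
                   unname(genome$length)))
  a <- aligned[aligned$mapped == TRUE, ]
  lines <- character(0)
  if (nrow(a)) {
    xg <- ifelse(a$strand %in% c("OT", "CTOT"), "CT", "GA")
    xr <- ifelse(a$strand %in% c("OT", "OB"), "CT", "GA")
    xr2 <- ifelse(xr == "CT", "GA", "CT")  # mate read conversion is opposite
    mk <- function(mate) {
      st <- if (mate == 1L) a$start1 else a$start2
      mst <- if (mate == 1L) a$start2 else a$start1
      or <- if (mate == 1L) a$orient1 else a$orient2
      sq <- if (mate == 1L) a$seq1 else a$seq2
      ql <- if (mate == 1L) a$qual1 else a$qual2
      rev <- or == "R"
      sq <- ifelse(rev, revcomp(sq), sq)
      ql <- ifelse(rev, vapply(strsplit(ql, ""), function(x)
        paste(rev(x), collapse = ""), ""), ql)
      # mates are always opposite-oriented in this ungapped model
      flag <- 1L + 2L + ifelse(rev, 16L, 0L) + ifelse(rev, 0L, 32L) +
        ifelse(mate == 1L, 64L, 128L)
      tlen0 <- pmax(a$start1, a$start2) + a$read_len -
        pmin(a$start1, a$start2)
      tlen <- ifelse(st <= mst, tlen0, -tlen0)
      sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s\tXG:Z:%s\tXR:Z:%s",
              a$id, flag, a$chrom, st + 1L, 42L, a$read_len, mst + 1L,
              tlen, sq, ql, xg,
              if (mate == 1L) xr else xr2)
    }
    lines <- c(rbind(mk(1L), mk(2L)))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
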