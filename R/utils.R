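# internal helpers shared across modules

#' @import data.table
#' @importFrom stats pnorm p.adjust rbeta rbinom rpois rnorm runif qbeta
#'   setNames ks.test pwilcox psignrank median wilcox.test
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# vectorised reverse complement on plain character vectors
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# C->T / G->A reduced-alphabet views used for three-letter alignment
ct_convert <- function(x) chartr("C", "T", x)
ga_convert <- function(x) chartr("G", "A", x)

# hamming distance between equal-length string vectors (fixed length L)
hamming <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  L <- nchar(a[1L])
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = length(a), ncol = L, byrow = TRUE)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE),
               nrow = length(b), ncol = L, byrow = TRUE)
  as.integer(rowSums(am != bm))
}

# fast in-place single-base substitutions on one sequence string
substitute_bases <- function(seq, pos0, bases) {
  r <- charToRaw(seq)
  r[pos0 + 1L] <- charToRaw(paste(bases, collapse = ""))
  rawToChar(r)
}

# extract single bases at 0-based positions of one sequence string
base_at <- function(seq, pos0) {
  substring(seq, pos0 + 1L, pos0 + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[strainmeth] ", ...)

#' Base-pair Jaccard index between two interval sets
#'
#' Intervals are 0-based half-open data.frames with chrom/start/end columns;
#' intervals within a set may overlap (each set is reduced first).
#'
#' @param a,b interval data.frames.
#' @return Jaccard index of the covered base sets, or \code{NA} when both
#'   sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  ga <- intervals_to_granges(a)
  gb <- intervals_to_granges(b)
  ga <- GenomicRanges::reduce(ga)
  gb <- GenomicRanges::reduce(gb)
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

# 0-based half-open data.frame -> GRanges (1-based closed)
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}
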