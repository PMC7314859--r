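#' Reference genome container
#'
#' Holds an ordered set of chromosome sequences together with a chromosome
#' class map (autosome / X / Y / MT).  Sequences are stored as uppercase
#' character strings restricted to the alphabet A, C, G, T, N.  All
#' coordinates used by the package are 0-based half-open; conversion to the
#' 1-based conventions of FASTA-adjacent formats (VCF, SAM, coverage files)
#' happens only at file boundaries.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param chrom_class optional named character vector mapping chromosome
#'   names to one of "autosome", "X", "Y", "MT".  When missing, classes are
#'   inferred from chromosome names (\code{chrX}/\code{X} patterns and so
#'   on); everything unmatched is an autosome.
#' @return an object of class \code{ref_genome} with elements \code{seq}
#'   (named character), \code{class} (named character) and \code{length}
#'   (named integer).
#' @export
ref_genome <- function(sequences, chrom_class = NULL) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  stopifnot(is.character(sequences), length(sequences) > 0)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("chromosome sequences must be nonempty")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence alphabet restricted to ACGTN; offending chromosome: ",
         names(sequences)[bad][1L])
  if (is.null(chrom_class)) chrom_class <- infer_chrom_class(names(sequences))
  chrom_class <- chrom_class[names(sequences)]
  if (anyNA(chrom_class)) stop("chrom_class must cover every chromosome")
  if (!all(chrom_class %in% c("autosome", "X", "Y", "MT")))
    stop("chromosome classes must be autosome, X, Y or MT")
  structure(list(seq = sequences,
                 class = setNames(as.character(chrom_class), names(sequences)),
                 length = setNames(nchar(sequences), names(sequences))),
            class = "ref_genome")
}

infer_chrom_class <- function(nm) {
  cls <- rep("autosome", length(nm))
  cls[grepl("^(chr)?X$", nm, ignore.case = TRUE)] <- "X"
  cls[grepl("^(chr)?Y$", nm, ignore.case = TRUE)] <- "Y"
  cls[grepl("^(chr)?(M|MT)$", nm, ignore.case = TRUE)] <- "MT"
  setNames(cls, nm)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$seq), "chromosome(s),",
      format(sum(as.numeric(x$length)), big.mark = ","), "bp\n")
  for (nm in names(x$seq))
    cat(sprintf("  %-8s %10d bp  [%s]\n", nm, x$length[[nm]], x$class[[nm]]))
  invisible(x)
}

#' Read / write a reference genome as FASTA
#'
#' Thin wrappers around \pkg{Biostrings} FASTA I/O (sequences wrapped at 60
#' columns on output).
#'
#' @param path file path.
#' @param chrom_class see \code{\link{ref_genome}}.
#' @return \code{read_genome_fasta} returns a \code{ref_genome}.
#' @export
read_genome_fasta <- function(path, chrom_class = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ref_genome(as.character(ss), chrom_class = chrom_class)
}

#' @param genome a \code{ref_genome}.
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' SNP table constructor
#'
#' Validated table of biallelic substitutions distinguishing the two
#' haplotype genomes.  \code{allele1} must equal the genome1 base at
#' \code{pos}; records are sorted by (chrom, pos).  The three
#' informativeness flags are filled by
#' \code{\link{annotate_snp_informativeness}}.
#'
#' @param chrom,pos,allele1,allele2 record fields; \code{pos} is 0-based.
#' @param genome optional \code{ref_genome} used to validate positions and
#'   reference alleles.
#' @return data.frame of class \code{snp_table} with columns chrom, pos,
#'   allele1, allele2, in_cpg, informative_ot, informative_ob.
#' @export
snp_table <- function(chrom, pos, allele1, allele2, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   allele1 = toupper(allele1), allele2 = toupper(allele2),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(nchar(df$allele1) == 1L & nchar(df$allele2) == 1L &
             df$allele1 %in% BASES & df$allele2 %in% BASES))
      stop("alleles must be single A/C/G/T bases (substitutions only)")
    if (any(df$allele1 == df$allele2)) stop("allele1 must differ from allele2")
    if (!is.null(genome)) {
      if (!all(df$chrom %in% names(genome$seq)))
        stop("SNP chromosome absent from genome: ",
             setdiff(df$chrom, names(genome$seq))[1L])
      if (any(df$pos < 0L | df$pos >= genome$length[df$chrom]))
        stop("SNP position outside chromosome bounds")
      refbase <- mapply(function(ch, p) base_at(genome$seq[[ch]], p),
                        df$chrom, df$pos, USE.NAMES = FALSE)
      bad <- refbase != df$allele1
      if (any(bad))
        stop(sprintf("allele1 mismatches genome1 at %s:%d (genome %s, table %s)",
                     df$chrom[bad][1L], df$pos[bad][1L] + 1L,
                     refbase[bad][1L], df$allele1[bad][1L]))
      ord <- order(match(df$chrom, names(genome$seq)), df$pos)
    } else {
      ord <- order(df$chrom, df$pos)
    }
    df <- df[ord, , drop = FALSE]
    if (anyDuplicated(df[c("chrom", "pos")]))
      stop("duplicate SNP positions")
  }
  df$in_cpg <- rep(NA, nrow(df))
  df$informative_ot <- rep(NA, nrow(df))
  df$informative_ob <- rep(NA, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Load a SNP table from VCF or TSV
#'
#' Accepts either a VCF v4 file (CHROM/POS/REF/ALT; only biallelic
#' substitution records are used) or a headerless four-column TSV
#' (\code{chrom<TAB>pos1based<TAB>ref<TAB>alt}).  Indel and multi-allelic
#' records are skipped and counted (indels carry no usable information for
#' substitution-only genome reconstruction); a record whose reference base
#' does not match genome1 is a validation error.
#'
#' @param path input file.
#' @param genome genome1 as a \code{ref_genome}.
#' @param format "auto" (by extension), "vcf" or "tsv".
#' @return a \code{\link{snp_table}}; the number of skipped records is kept
#'   in \code{attr(, "skipped")}.
#' @export
load_snp_table <- function(path, genome, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- v@fix  # fixed columns are a matrix regardless of record count
    chrom <- fx[, "CHROM"]; pos1 <- as.integer(fx[, "POS"])
    ref <- toupper(fx[, "REF"]); alt <- toupper(fx[, "ALT"])
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "[\t ]+")
    nfield <- lengths(parts)
    if (any(nfield < 4L))
      stop("unparseable SNP line ", which(nfield < 4L)[1L],
           ": expected chrom, pos, ref, alt")
    chrom <- vapply(parts, `[`, "", 1L)
    pos1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(pos1))
      stop("unparseable SNP line ", which(is.na(pos1))[1L],
           ": position is not an integer")
    ref <- toupper(vapply(parts, `[`, "", 3L))
    alt <- toupper(vapply(parts, `[`, "", 4L))
  }
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES & !grepl(",", alt, fixed = TRUE)
  skipped <- sum(!keep)
  if (skipped > 0)
    msg(skipped, " indel/multi-allelic/non-ACGT record(s) skipped")
  if (!all(chrom[keep] %in% names(genome$seq)))
    stop("SNP chromosome absent from genome: ",
         setdiff(chrom[keep], names(genome$seq))[1L])
  out <- snp_table(chrom[keep], pos1[keep] - 1L, ref[keep], alt[keep],
                   genome = genome)
  attr(out, "skipped") <- skipped
  out
}

#' Export a SNP table as TSV
#'
#' Writes chrom, 1-based position, both alleles and the three boolean
#' informativeness flags.
#' @param snps a \code{snp_table}.
#' @param path output file.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.frame(chrom = snps$chrom, pos = snps$pos + 1L,
                    ref = snps$allele1, alt = snps$allele2,
                    in_cpg = snps$in_cpg,
                    informative_ot = snps$informative_ot,
                    informative_ob = snps$informative_ob)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a SNP table written by \code{write_snp_table}
#' @inheritParams load_snp_table
#' @export
read_snp_table <- function(path, genome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- snp_table(df$chrom, df$pos - 1L, df$ref, df$alt, genome = genome)
  if (!is.null(df$in_cpg)) {
    key <- paste(out$chrom, out$pos)
    idx <- match(key, paste(df$chrom, df$pos - 1L))
    out$in_cpg <- as.logical(df$in_cpg)[idx]
    out$informative_ot <- as.logical(df$informative_ot)[idx]
    out$informative_ob <- as.logical(df$informative_ob)[idx]
  }
  out
}

#' Reconstruct the alternate strain genome
#'
#' Substitutes \code{allele2} at every SNP position of genome1, yielding the
#' second haplotype genome.  Chromosomes classed Y or MT are dropped from
#' the result (no SNP data exists for them in an inter-strain cross of
#' female lines, and the original study omitted them for the same reason).
#'
#' @param genome1 reference \code{ref_genome}.
#' @param snps validated \code{snp_table}.
#' @return the alternate \code{ref_genome}.
#' @export
reconstruct_alternate_genome <- function(genome1, snps) {
  keep <- names(genome1$seq)[!genome1$class %in% c("Y", "MT")]
  seqs <- genome1$seq[keep]
  if (nrow(snps)) {
    sp <- split(seq_len(nrow(snps)), snps$chrom)
    for (ch in names(sp)) {
      if (!ch %in% keep) next
      i <- sp[[ch]]
      seqs[[ch]] <- substitute_bases(seqs[[ch]], snps$pos[i], snps$allele2[i])
    }
  }
  ref_genome(seqs, chrom_class = genome1$class[keep])
}

#' Index CpG sites
#'
#' Returns, per chromosome, the sorted 0-based positions p with
#' sequence[p] == "C" and sequence[p+1] == "G".  A CpG site is always
#' identified by the position of its plus-strand C.
#'
#' @param genome a \code{ref_genome}.
#' @return named list of integer vectors.
#' @export
index_cpg_sites <- function(genome) {
  lapply(genome$seq, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  })
}

#' Annotate conversion-aware SNP informativeness
#'
#' Flags each SNP for (i) overlap with a CpG dinucleotide in either genome
#' (either base of the pair) and (ii) usability for allele calls on reads
#' from each original strand.  Bisulfite conversion reads unmethylated C as
#' T on original-top-derived reads, so a \{C,T\} SNP is uninformative there;
#' symmetrically \{G,A\} SNPs are uninformative on original-bottom-derived
#' reads.  CpG-overlapping SNPs are informative for neither strand, because
#' the C/T (or G/A) state at a CpG reflects methylation, not haplotype.
#'
#' @param snps \code{snp_table}.
#' @param genome1,genome2 the two haplotype genomes.
#' @return the \code{snp_table} with the three flags filled.
#' @export
annotate_snp_informativeness <- function(snps, genome1, genome2) {
  n <- nrow(snps)
  if (n == 0L) return(snps)
  in_cpg <- logical(n)
  for (g in list(genome1, genome2)) {
    sp <- split(seq_len(n), snps$chrom)
    for (ch in names(sp)) {
      if (!ch %in% names(g$seq)) next
      i <- sp[[ch]]
      s <- g$seq[[ch]]; L <- g$length[[ch]]
      p <- snps$pos[i]
      here <- base_at(s, p)
      nxt <- ifelse(p + 1L < L, base_at(s, p + 1L), "")
      prv <- ifelse(p - 1L >= 0L, base_at(s, p - 1L), "")
      in_cpg[i] <- in_cpg[i] |
        (here == "C" & nxt == "G") | (prv == "C" & here == "G")
    }
  }
  lo <- pmin(snps$allele1, snps$allele2)
  hi <- pmax(snps$allele1, snps$allele2)
  blocked_ot <- lo == "C" & hi == "T"
  blocked_ob <- lo == "A" & hi == "G"
  snps$in_cpg <- in_cpg
  snps$informative_ot <- !blocked_ot & !in_cpg
  snps$informative_ob <- !blocked_ob & !in_cpg
  snps
}

#' CpG sites destroyed or created by SNPs
#'
#' A CpG dinucleotide present in only one of the two haplotype genomes
#' cannot be scored consistently across alleles; methylation extraction
#' skips these sites.
#'
#' @param genome1,genome2 the two haplotype genomes.
#' @return data.frame (chrom, pos) of plus-strand C coordinates to exclude.
#' @export
snp_destroyed_cpgs <- function(genome1, genome2) {
  c1 <- index_cpg_sites(genome1)
  c2 <- index_cpg_sites(genome2)
  shared <- intersect(names(c1), names(c2))
  out <- lapply(shared, function(ch) {
    d <- c(setdiff(c1[[ch]], c2[[ch]]), setdiff(c2[[ch]], c1[[ch]]))
    if (length(d)) data.frame(chrom = ch, pos = sort(d)) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = integer(0))
  out
}
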