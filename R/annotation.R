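#' Gene / CGI / repeat annotation container
#'
#' @param genes data.frame with columns id, chrom, strand ("+"/"-"), tss,
#'   tes (0-based; for minus-strand genes tss > tes), is_pcg (logical flag
#'   marking Polycomb-target developmental genes).
#' @param cgis data.frame chrom/start/end (0-based half-open) of CpG islands.
#' @param repeats data.frame chrom/start/end/class of repeat-like intervals.
#' @param chrom_class named character vector (see \code{\link{ref_genome}}).
#' @return object of class \code{gene_annotation}.
#' @export
gene_annotation <- function(genes, cgis = NULL, repeats = NULL,
                            chrom_class = NULL) {
  empty_iv <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))
  if (is.null(cgis)) cgis <- empty_iv
  if (is.null(repeats)) repeats <- cbind(empty_iv, class = character(0))
  stopifnot(all(c("id", "chrom", "strand", "tss", "tes") %in% names(genes)))
  if (is.null(genes$is_pcg)) genes$is_pcg <- FALSE
  ok <- ifelse(genes$strand == "+", genes$tss < genes$tes, genes$tss > genes$tes)
  if (nrow(genes) && !all(ok))
    stop("TSS/TES orientation inconsistent with strand for gene ",
         genes$id[!ok][1L])
  if (is.null(chrom_class))
    chrom_class <- infer_chrom_class(unique(c(genes$chrom, cgis$chrom,
                                              repeats$chrom)))
  structure(list(genes = genes, cgis = cgis, repeats = repeats,
                 chrom_class = chrom_class),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes (",
      sum(x$genes$is_pcg), "PcG-flagged ),", nrow(x$cgis), "CGIs,",
      nrow(x$repeats), "repeat-like intervals\n")
  invisible(x)
}

# gene extent [min(tss,tes), max(tss,tes)) as 0-based half-open interval
gene_body_intervals <- function(genes) {
  data.frame(region_id = genes$id, chrom = genes$chrom,
             start = pmin(genes$tss, genes$tes),
             end = pmax(genes$tss, genes$tes),
             stringsAsFactors = FALSE)
}

# TSS +/- flank, strand independent, clipped at 0 (right clipping happens
# against chromosome length where a genome is available)
gene_tss_intervals <- function(genes, flank = 1000L) {
  data.frame(region_id = genes$id, chrom = genes$chrom,
             start = pmax(0L, genes$tss - flank),
             end = genes$tss + flank,
             stringsAsFactors = FALSE)
}

#' Annotation I/O
#'
#' Genes travel as a TSV with columns id, chrom, strand, tss, tes (1-based
#' inclusive on disk), is_pcg; CGI and repeat intervals as BED (0-based
#' half-open, read and written through \pkg{rtracklayer}).
#'
#' @param path file path.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$tss <- df$tss - 1L
  df$tes <- df$tes - 1L
  df$is_pcg <- as.logical(df$is_pcg %||% FALSE)
  df
}

#' @param genes gene data.frame (internal 0-based representation).
#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$tss <- out$tss + 1L
  out$tes <- out$tes + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param name_col optional metadata column to carry through as interval class.
#' @rdname read_gene_table
#' @export
read_bed_intervals <- function(path, name_col = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (name_col && !is.null(gr$name)) out$class <- gr$name
  out
}

#' @param intervals data.frame chrom/start/end (0-based half-open).
#' @rdname read_gene_table
#' @export
write_bed_intervals <- function(intervals, path) {
  gr <- intervals_to_granges(intervals)
  if (!is.null(intervals$class)) gr$name <- intervals$class
  if (!is.null(intervals$region_id)) gr$name <- intervals$region_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
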