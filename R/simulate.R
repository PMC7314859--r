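#' Simulation configuration
#'
#' Defines the study conditions emulated by the toy-data generator: a small
#' diploid genome with strain SNPs, CpG islands at promoters, a
#' Polycomb-target ("PcG") gene subset, an X-like chromosome, and
#' genotype-dependent methylomes sampled per feature class from Beta laws.
#' Genotypes mirror the biology under study: \code{WT} (globally
#' methylated, CGIs unmethylated), \code{KO3A} (Dnmt3a-null-like:
#' hypomethylation at PcG promoters and gene bodies) and \code{KO3B}
#' (Dnmt3b-null-like: hypomethylation at X-linked CGIs, X non-CGI sites and
#' repeat-like intervals).
#'
#' @param n_autosomes,chrom_length,include_X genome layout.
#' @param n_genes_per_chrom,pcg_fraction,cgi_at_promoter_prob gene layout;
#'   PcG flags are placed on autosomal genes only.
#' @param n_repeats_per_chrom,repeat_length repeat-like labeled intervals
#'   (labels only; no sequence-level repeats).
#' @param snp_density SNPs per bp between the two strains.
#' @param snp_cpg_fraction fraction of SNPs forced inside CpG dinucleotides.
#' @param genotype one of "WT", "KO3A", "KO3B".
#' @param meth_profile data.frame(class, genotype, alpha, beta); see
#'   \code{\link{default_meth_profile}}.
#' @param coverage mean read-pair (fragment) depth per CpG site.
#' @param read_length,fragment_mean,fragment_sd read geometry (bp).
#' @param conversion_rate probability that an unmethylated C reads as T.
#' @param failed_conversion_rate probability that a methylated C reads as T.
#' @param seq_error_rate per-base substitution error rate.
#' @param duplicate_rate fraction of fragments re-emitted as PCR-style
#'   duplicates (exists solely to exercise deduplication).
#' @param pbat emit complementary-strand (CTOT/CTOB) reads instead of the
#'   directional OT/OB protocol.
#' @param allele_effect optional list(class=, delta=) lowering the allele-2
#'   methylation probability by \code{delta} within one feature class.
#' @param const_qual constant Phred quality written to FASTQ.
#' @param seed integer seed; all generator stages are deterministic in it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_autosomes = 2L, chrom_length = 300000L,
                       include_X = TRUE, n_genes_per_chrom = 25L,
                       pcg_fraction = 0.2, cgi_at_promoter_prob = 0.7,
                       n_repeats_per_chrom = 8L, repeat_length = 2000L,
                       snp_density = 1 / 150, snp_cpg_fraction = 0.05,
                       genotype = c("WT", "KO3A", "KO3B"),
                       meth_profile = default_meth_profile(),
                       coverage = 20, read_length = 100L,
                       fragment_mean = 200L, fragment_sd = 20L,
                       conversion_rate = 0.99, failed_conversion_rate = 0.01,
                       seq_error_rate = 0.001, duplicate_rate = 0,
                       pbat = FALSE, allele_effect = NULL,
                       const_qual = 40L, seed = 1L) {
  genotype <- match.arg(genotype)
  probs <- c(cgi_at_promoter_prob, pcg_fraction, snp_cpg_fraction,
             conversion_rate, failed_conversion_rate, seq_error_rate,
             duplicate_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (coverage <= 0 && coverage != 0) stop("coverage must be positive")
  if (coverage < 0) stop("coverage must be >= 0")
  if (fragment_mean < read_length)
    stop("fragment_mean must be >= read_length")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Default genotype-dependent methylation profile
#'
#' Beta(alpha, beta) laws per (feature class, genotype).  The wild-type
#' background is Beta(8, 2) (mean 0.8, the global level of a methylated
#' somatic genome); knockouts lower the mean of their target classes by
#' about 0.4.  Effect sizes are synthetic choices made for testability, not
#' estimates from any dataset.
#'
#' @return data.frame(class, genotype, alpha, beta).
#' @export
default_meth_profile <- function() {
  row <- function(class, genotype, a, b)
    data.frame(class = class, genotype = genotype, alpha = a, beta = b)
  rbind(
    row("background",   "WT", 8, 2), row("background",   "KO3A", 8, 2),
    row("background",   "KO3B", 8, 2),
    row("x_background", "WT", 8, 2), row("x_background", "KO3A", 8, 2),
    row("x_background", "KO3B", 4, 6),
    row("cgi",          "WT", 1, 19), row("cgi",         "KO3A", 1, 19),
    row("cgi",          "KO3B", 1, 19),
    row("x_cgi",        "WT", 9, 11), row("x_cgi",       "KO3A", 9, 11),
    row("x_cgi",        "KO3B", 1, 19),
    row("pcg_tss",      "WT", 7, 3), row("pcg_tss",      "KO3A", 3, 7),
    row("pcg_tss",      "KO3B", 7, 3),
    row("pcg_body",     "WT", 8, 2), row("pcg_body",     "KO3A", 4, 6),
    row("pcg_body",     "KO3B", 8, 2),
    row("repeat",       "WT", 8, 2), row("repeat",       "KO3A", 8, 2),
    row("repeat",       "KO3B", 4, 6)
  )
}

# random background sequence at GC ~ 0.42
random_sequence <- function(n) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
}

# CpG-enriched island sequence of (at least) the requested length
cgi_sequence <- function(n) {
  tokens <- sample(c("CG", "A", "C", "G", "T"), ceiling(n / 1.15),
                   replace = TRUE, prob = c(0.13, 0.17, 0.27, 0.27, 0.16))
  s <- paste(tokens, collapse = "")
  substr(s, 1L, n)
}

#' Build a toy diploid genome with annotations and SNPs
#'
#' Generates a random genome, places non-overlapping genes with optional
#' promoter CpG islands, flags an autosomal PcG-target gene subset, lays
#' down repeat-like labeled intervals, and plants biallelic SNPs at the
#' configured density.  Deterministic under \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list(genome, annotation, snps): genome1 as \code{ref_genome},
#'   a \code{gene_annotation}, and an informativeness-annotated
#'   \code{snp_table}.
#' @export
build_toy_genome <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_autosomes))
  if (config$include_X) chroms <- c(chroms, "chrX")

  ng <- config$n_genes_per_chrom
  slot <- floor(L / ng)
  if (slot < 3000L)
    stop("infeasible packing: ", ng, " genes do not fit in ", L, " bp")

  seqs <- setNames(vapply(chroms, function(ch) random_sequence(L), ""),
                   chroms)
  genes <- list(); cgis <- list(); reps <- list()
  for (ch in chroms) {
    glen <- sample(2000:min(8000L, slot - 1200L), ng, replace = TRUE)
    off <- vapply(slot - glen - 1100L, function(m) sample.int(m, 1L) + 1000L, 0L)
    gstart <- (seq_len(ng) - 1L) * slot + off
    gend <- gstart + glen
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    tss <- ifelse(strand == "+", gstart, gend - 1L)
    tes <- ifelse(strand == "+", gend - 1L, gstart)
    is_pcg <- rep(FALSE, ng)
    if (ch != "chrX" && config$pcg_fraction > 0)
      is_pcg[sample.int(ng, round(ng * config$pcg_fraction))] <- TRUE
    g <- data.frame(id = sprintf("%s_g%02d", ch, seq_len(ng)), chrom = ch,
                    strand = strand, tss = as.integer(tss),
                    tes = as.integer(tes), is_pcg = is_pcg,
                    stringsAsFactors = FALSE)
    genes[[ch]] <- g
    has_cgi <- runif(ng) < config$cgi_at_promoter_prob
    if (any(has_cgi)) {
      cs <- pmax(0L, as.integer(tss[has_cgi]) - 500L)
      ce <- pmin(L, cs + 1000L)
      for (k in seq_along(cs)) {
        isl <- cgi_sequence(ce[k] - cs[k])
        substr(seqs[[ch]], cs[k] + 1L, ce[k]) <- isl
      }
      cgis[[ch]] <- data.frame(chrom = ch, start = cs, end = ce)
    }
    # repeat-like intervals live in the inter-gene gaps
    if (config$n_repeats_per_chrom > 0) {
      gap_start <- gend[-ng] + 100L
      gap_end <- gstart[-1L] - 100L - config$repeat_length
      ok <- which(gap_end > gap_start)
      take <- ok[sample.int(length(ok),
                            min(config$n_repeats_per_chrom, length(ok)))]
      rs <- vapply(take, function(i)
        sample(gap_start[i]:gap_end[i], 1L), 0L)
      reps[[ch]] <- data.frame(chrom = ch, start = as.integer(rs),
                               end = as.integer(rs) + config$repeat_length,
                               class = "repeat")
    }
  }
  genes <- do.call(rbind, genes)
  cgis <- do.call(rbind, cgis)
  reps <- do.call(rbind, reps)
  genome <- ref_genome(seqs)
  ann <- gene_annotation(genes, cgis, reps, chrom_class = genome$class)

  # plant SNPs: a target fraction inside CpGs, the rest outside
  cpg <- index_cpg_sites(genome)
  snp <- list()
  for (ch in chroms) {
    n_snp <- rbinom(1L, L, config$snp_density)
    cpg_pos <- sort(unique(c(cpg[[ch]], cpg[[ch]] + 1L)))
    n_in <- rbinom(1L, n_snp, config$snp_cpg_fraction)
    p_in <- if (n_in > 0) sample(cpg_pos, min(n_in, length(cpg_pos))) else integer(0)
    pool <- setdiff(seq_len(L - 2L), cpg_pos)  # avoid final base, keep simple
    p_out <- sample(pool, n_snp - length(p_in))
    pos <- sort(unique(c(p_in, p_out)))
    a1 <- base_at(seqs[[ch]], pos)
    a2 <- vapply(a1, function(b) sample(setdiff(BASES, b), 1L), "",
                 USE.NAMES = FALSE)
    snp[[ch]] <- data.frame(chrom = ch, pos = pos, a1 = a1, a2 = a2)
  }
  snp <- do.call(rbind, snp)
  snps <- snp_table(snp$chrom, snp$pos, snp$a1, snp$a2, genome = genome)
  genome2 <- reconstruct_alternate_genome(genome, snps)
  snps <- annotate_snp_informativeness(snps, genome, genome2)
  list(genome = genome, annotation = ann, snps = snps)
}

# most specific feature class per CpG site; PcG promoter/body outrank the
# generic CGI class (the knockout effect acts on the PcG region as a whole),
# CGIs outrank repeats and chromosome background
classify_sites <- function(sites_dt, annotation) {
  prec <- c("pcg_tss", "x_cgi", "cgi", "pcg_body", "repeat", "x_background",
            "background")
  cls <- rep("background", nrow(sites_dt))
  is_x <- annotation$chrom_class[sites_dt$chrom] == "X"
  cls[is_x] <- "x_background"
  gr_sites <- GenomicRanges::GRanges(sites_dt$chrom,
                                     IRanges::IRanges(sites_dt$pos + 1L,
                                                      width = 1L))
  hit <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(integer(0))
    unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_sites, intervals_to_granges(iv))))
  }
  assign_cls <- function(idx, label) {
    keep <- idx[match(cls[idx], prec) > match(label, prec)]
    cls[keep] <<- label
  }
  assign_cls(hit(annotation$repeats), "repeat")
  pcg <- annotation$genes[annotation$genes$is_pcg, , drop = FALSE]
  assign_cls(hit(gene_body_intervals(pcg)), "pcg_body")
  cgi_idx <- hit(annotation$cgis)
  assign_cls(cgi_idx[!is_x[cgi_idx]], "cgi")
  assign_cls(cgi_idx[is_x[cgi_idx]], "x_cgi")
  assign_cls(hit(gene_tss_intervals(pcg)), "pcg_tss")
  cls
}

#' Assign a genotype-dependent methylome
#'
#' Draws a methylation probability for every CpG site from the Beta law of
#' its most specific feature class under each requested genotype.  Draws
#' are coupled through a common per-site uniform, so classes whose law does
#' not differ between two genotypes share identical values — matched
#' comparisons on unaffected features are exactly null.
#'
#' @param annotation a \code{gene_annotation}.
#' @param genome genome1 (\code{ref_genome}); CpG sites are indexed on it.
#' @param config \code{sim_config}.
#' @param genotypes genotypes to realize (always includes "WT").
#' @return object of class \code{methylome}: data.table with chrom, pos,
#'   class and one probability column \code{p_<genotype>} per genotype,
#'   plus a \code{planted} attribute listing every interval whose
#'   class-genotype law differs from WT (chrom, start, end, class,
#'   genotype, direction, effect).
#' @export
assign_methylome <- function(annotation, genome, config,
                             genotypes = unique(c("WT", config$genotype))) {
  set.seed(config$seed + 7L)
  cpg <- index_cpg_sites(genome)
  dt <- data.table::rbindlist(lapply(names(cpg), function(ch)
    data.table::data.table(chrom = ch, pos = cpg[[ch]])))
  dt[, class := classify_sites(dt, annotation)]
  prof <- config$meth_profile
  need <- expand.grid(class = unique(dt$class), genotype = genotypes,
                      stringsAsFactors = FALSE)
  have <- paste(prof$class, prof$genotype)
  missing <- !paste(need$class, need$genotype) %in% have
  if (any(missing))
    stop("meth_profile lacks class/genotype: ",
         paste(need$class[missing], need$genotype[missing])[1L])
  u <- runif(nrow(dt))
  for (g in genotypes) {
    pg <- prof[prof$genotype == g, ]
    a <- pg$alpha[match(dt$class, pg$class)]
    b <- pg$beta[match(dt$class, pg$class)]
    data.table::set(dt, j = paste0("p_", g), value = qbeta(u, a, b))
  }
  planted <- planted_regions(annotation, genome, config, genotypes)
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(dt, planted = planted, config = config, class =
              c("methylome", class(dt)))
}

# intervals whose class law differs from WT for each KO genotype
planted_regions <- function(annotation, genome, config, genotypes) {
  prof <- config$meth_profile
  mean_of <- function(class, g) {
    r <- prof[prof$class == class & prof$genotype == g, ]
    r$alpha / (r$alpha + r$beta)
  }
  out <- list()
  class_intervals <- function(class) {
    pcg <- annotation$genes[annotation$genes$is_pcg, , drop = FALSE]
    is_x <- annotation$chrom_class[annotation$cgis$chrom] == "X"
    switch(class,
      pcg_tss = gene_tss_intervals(pcg)[c("chrom", "start", "end")],
      pcg_body = gene_body_intervals(pcg)[c("chrom", "start", "end")],
      x_cgi = annotation$cgis[is_x, , drop = FALSE],
      cgi = annotation$cgis[!is_x, , drop = FALSE],
      "repeat" = annotation$repeats[c("chrom", "start", "end")],
      x_background = {
        xc <- names(genome$class)[genome$class == "X"]
        data.frame(chrom = xc, start = 0L,
                   end = unname(genome$length[xc]))
      },
      NULL)
  }
  for (g in setdiff(genotypes, "WT")) {
    for (cl in unique(prof$class)) {
      eff <- mean_of(cl, "WT") - mean_of(cl, g)
      if (abs(eff) < 1e-12) next
      iv <- class_intervals(cl)
      if (is.null(iv) || nrow(iv) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = iv$chrom, start = iv$start, end = iv$end, class = cl,
        genotype = g,
        direction = if (eff > 0) "WT_gt_KO" else "KO_gt_WT",
        effect = eff, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               class = character(0), genotype = character(0),
               direction = character(0), effect = numeric(0))
}

# per-site probability vector for (genotype, allele) at given site keys
site_probability <- function(methylome, keys, genotype, allele,
                             config = attr(methylome, "config")) {
  col <- paste0("p_", genotype)
  if (!col %in% names(methylome))
    stop("methylome does not carry genotype ", genotype)
  p <- methylome[keys, on = c("chrom", "pos")][[col]]
  ae <- config$allele_effect
  if (!is.null(ae) && allele == 2L) {
    cls <- methylome[keys, on = c("chrom", "pos")]$class
    p <- ifelse(cls == ae$class, pmax(0, p - ae$delta), p)
  }
  p
}
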