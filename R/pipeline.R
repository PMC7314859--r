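# staged end-to-end pipeline with per-stage manifests

#' Pipeline configuration
#'
#' Bundles the generator settings, the test/caller thresholds and the
#' protocol mode.  \code{mode = "capture"} emulates a capture design whose
#' probes target the original top strand: only original-bottom evidence is
#' used, fragments are not deduplicated (capture depth is real depth), and
#' the site-level coverage floor is raised to 50x; \code{"wgbs"} uses both
#' strands, deduplicates, and floors at 5x.
#'
#' @param sim \code{\link{sim_config}}; its \code{genotype} names the
#'   knockout compared against WT (must not be "WT").
#' @param params \code{\link{test_params}}.
#' @param mode "wgbs" or "capture".
#' @param trim \code{\link{trim_windows}}.
#' @param assign_policy allele-vote policy ("strict" or "majority").
#' @param max_mismatches alignment mismatch budget per mate.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(n_autosomes = 1L,
                                             chrom_length = 150000L,
                                             n_genes_per_chrom = 12L,
                                             coverage = 6,
                                             genotype = "KO3A"),
                            params = test_params(),
                            mode = c("wgbs", "capture"),
                            trim = trim_windows(),
                            assign_policy = "strict",
                            max_mismatches = 4L) {
  mode <- match.arg(mode)
  if (sim$genotype == "WT")
    stop("sim$genotype must name a knockout to compare against WT")
  if (mode == "capture") params$site_min_cov <- 50L
  cfg <- list(sim = sim, params = params, mode = mode, trim = trim,
              assign_policy = assign_policy,
              max_mismatches = max_mismatches)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- c("simulate", "reconstruct", "align", "split",
                     "extract", "diff", "dmr", "summarize")

pipe_path <- function(run_dir, ...) file.path(run_dir, paste0(...))

require_inputs <- function(paths, stage, producer) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' requires missing input ", missing[1L],
         " (run stage '", producer, "' first)")
  invisible(TRUE)
}

write_manifest <- function(run_dir, stage, outputs, extra = list()) {
  man <- c(list(stage = stage,
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                outputs = basename(outputs)), extra)
  jsonlite::write_json(man, pipe_path(run_dir, stage, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(man)
}

pipe_samples <- function(config) c("WT", config$sim$genotype)

#' Run one pipeline stage (or all of them)
#'
#' Stages and their artifacts, all inside \code{run_dir}:
#' \describe{
#'   \item{simulate}{toy genome (\code{genome1.fa}), SNP table
#'     (\code{snps.tsv}), annotation (\code{genes.tsv}, \code{cgis.bed},
#'     \code{repeats.bed}), methylome (\code{methylome.rds}), and one
#'     paired FASTQ sample per genotype (WT and the configured knockout)
#'     with truth sets (\code{truth_<sample>.rds}).}
#'   \item{reconstruct}{alternate genome \code{genome2.fa} and the
#'     informativeness-annotated SNP table \code{snps_annotated.rds}.}
#'   \item{align}{per sample and haplotype genome, aligned pairs
#'     (\code{aln_<sample>_g<1|2>.rds}).}
#'   \item{split}{dual-genome concordant pairs with allele verdicts
#'     (\code{split_<sample>.rds}) and the vote summaries
#'     (\code{assign_<sample>.tsv}).}
#'   \item{extract}{coverage files \code{<sample>.cov} (pooled) and
#'     \code{<sample>_allele<1|2>.cov}.}
#'   \item{diff}{site-level test records (\code{dml.tsv},
#'     \code{dml_records.rds}) and tiles (\code{dmt.tsv}).}
#'   \item{dmr}{regions (\code{dmrs.tsv}, \code{dmrs.bed}).}
#'   \item{summarize}{gene summaries (\code{genes_<sample>.tsv}), target
#'     genes and global statistics (\code{summary.json}).}
#' }
#' Each stage writes a JSON manifest \code{<stage>.json}; a stage whose
#' inputs are missing stops with an error naming the file and the stage
#' that produces it.  Everything is deterministic in \code{config$sim$seed}.
#'
#' @param stage one of the stages above, or "run-all".
#' @param config a \code{\link{pipeline_config}}.
#' @param run_dir working directory for artifacts (created if needed).
#' @return the stage manifest (invisibly); "run-all" returns the list of
#'   manifests.
#' @export
run_stage <- function(stage = c("run-all", pipeline_stages),
                      config = pipeline_config(), run_dir) {
  stage <- match.arg(stage)
  if (missing(run_dir)) stop("run_dir is required")
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  if (stage == "run-all") {
    mans <- lapply(pipeline_stages, run_stage, config = config,
                   run_dir = run_dir)
    names(mans) <- pipeline_stages
    return(invisible(mans))
  }
  fn <- get(paste0("stage_", stage), mode = "function")
  invisible(fn(config, run_dir))
}

stage_simulate <- function(config, run_dir) {
  sim <- config$sim
  world <- build_toy_genome(sim)
  genome1 <- world$genome
  write_genome_fasta(genome1, pipe_path(run_dir, "genome1.fa"))
  write_snp_table(world$snps, pipe_path(run_dir, "snps.tsv"))
  write_gene_table(world$annotation$genes, pipe_path(run_dir, "genes.tsv"))
  write_bed_intervals(world$annotation$cgis, pipe_path(run_dir, "cgis.bed"))
  write_bed_intervals(world$annotation$repeats,
                      pipe_path(run_dir, "repeats.bed"))
  genome2 <- reconstruct_alternate_genome(genome1, world$snps)
  meth <- assign_methylome(world$annotation, genome1, sim)
  saveRDS(meth, pipe_path(run_dir, "methylome.rds"))
  outs <- c("genome1.fa", "snps.tsv", "genes.tsv", "cgis.bed",
            "repeats.bed", "methylome.rds")
  n_pairs <- integer(0)
  for (i in seq_along(pipe_samples(config))) {
    smp <- pipe_samples(config)[i]
    res <- simulate_read_pairs(genome1, genome2, meth, sim,
                               genotype = smp, seed = sim$seed + 101L * i,
                               id_prefix = paste0(tolower(smp), "_"))
    write_fastq_pairs(res$reads, pipe_path(run_dir, smp))
    saveRDS(res$truth, pipe_path(run_dir, "truth_", smp, ".rds"))
    outs <- c(outs, paste0(smp, c("_1.fastq.gz", "_2.fastq.gz")),
              paste0("truth_", smp, ".rds"))
    n_pairs <- c(n_pairs, nrow(res$reads))
  }
  write_manifest(run_dir, "simulate", outs,
                 list(seed = sim$seed, genotypes = pipe_samples(config),
                      n_read_pairs = n_pairs))
}

stage_reconstruct <- function(config, run_dir) {
  ins <- pipe_path(run_dir, c("genome1.fa", "snps.tsv"))
  require_inputs(ins, "reconstruct", "simulate")
  genome1 <- read_genome_fasta(ins[1L])
  snps <- read_snp_table(ins[2L], genome = genome1)
  genome2 <- reconstruct_alternate_genome(genome1, snps)
  write_genome_fasta(genome2, pipe_path(run_dir, "genome2.fa"))
  snps <- annotate_snp_informativeness(snps, genome1, genome2)
  saveRDS(snps, pipe_path(run_dir, "snps_annotated.rds"))
  write_manifest(run_dir, "reconstruct",
                 c("genome2.fa", "snps_annotated.rds"),
                 list(n_snps = nrow(snps),
                      n_excluded_cpg_sites =
                        nrow(snp_destroyed_cpgs(genome1, genome2))))
}

stage_align <- function(config, run_dir) {
  smps <- pipe_samples(config)
  ins <- c(pipe_path(run_dir, c("genome1.fa", "genome2.fa")),
           pipe_path(run_dir, rep(smps, each = 2),
                     c("_1.fastq.gz", "_2.fastq.gz")))
  require_inputs(ins[1L], "align", "simulate")
  require_inputs(ins[2L], "align", "reconstruct")
  require_inputs(ins[-(1:2)], "align", "simulate")
  outs <- character(0); rates <- list()
  for (g in 1:2) {
    genome <- read_genome_fasta(pipe_path(run_dir, "genome", g, ".fa"))
    index <- build_converted_index(genome)
    for (smp in smps) {
      reads <- read_fastq_pairs(
        pipe_path(run_dir, smp, "_1.fastq.gz"),
        pipe_path(run_dir, smp, "_2.fastq.gz"))
      aln <- align_read_pairs(reads, index,
                              max_mismatches = config$max_mismatches)
      f <- paste0("aln_", smp, "_g", g, ".rds")
      saveRDS(aln, pipe_path(run_dir, f))
      outs <- c(outs, f)
      rates[[paste0(smp, "_g", g)]] <-
        mean(aln$mapped & aln$unique)
    }
  }
  write_manifest(run_dir, "align", outs, list(unique_mapping_rate = rates))
}

stage_split <- function(config, run_dir) {
  smps <- pipe_samples(config)
  ins <- c(pipe_path(run_dir, "snps_annotated.rds"),
           pipe_path(run_dir, "aln_", rep(smps, each = 2), "_g", 1:2,
                     ".rds"))
  require_inputs(ins[1L], "split", "reconstruct")
  require_inputs(ins[-1L], "split", "align")
  snps <- readRDS(ins[1L])
  outs <- character(0); stats <- list()
  for (smp in smps) {
    a1 <- readRDS(pipe_path(run_dir, "aln_", smp, "_g1.rds"))
    a2 <- readRDS(pipe_path(run_dir, "aln_", smp, "_g2.rds"))
    conc <- dual_map_concordance(a1, a2)
    asg <- assign_alleles(conc, snps, policy = config$assign_policy,
                          trim = config$trim)
    write_assignments(asg, pipe_path(run_dir, "assign_", smp, ".tsv"))
    pairs <- data.table::as.data.table(conc)
    pairs[, verdict := asg$verdict[match(id, asg$id)]]
    saveRDS(pairs, pipe_path(run_dir, "split_", smp, ".rds"))
    outs <- c(outs, paste0("assign_", smp, ".tsv"),
              paste0("split_", smp, ".rds"))
    stats[[smp]] <- list(
      n_concordant = nrow(pairs),
      assignment_rate = mean(asg$verdict %in% c("genome1", "genome2")))
  }
  write_manifest(run_dir, "split", outs, stats)
}

stage_extract <- function(config, run_dir) {
  smps <- pipe_samples(config)
  ins <- c(pipe_path(run_dir, c("genome1.fa", "genome2.fa")),
           pipe_path(run_dir, "split_", smps, ".rds"))
  require_inputs(ins[1:2], "extract", "simulate/reconstruct")
  require_inputs(ins[-(1:2)], "extract", "split")
  genome1 <- read_genome_fasta(ins[1L])
  genome2 <- read_genome_fasta(ins[2L])
  exclude <- snp_destroyed_cpgs(genome1, genome2)
  capture <- config$mode == "capture"
  outs <- character(0)
  for (smp in smps) {
    pairs <- readRDS(pipe_path(run_dir, "split_", smp, ".rds"))
    calls <- call_methylation(pairs, genome1, trim = config$trim,
                              exclude = exclude)
    if (capture)
      calls <- strand_restrict(calls, "original_bottom_only")
    write_coverage(aggregate_counts(calls, dedup = !capture, sample = smp),
                   pipe_path(run_dir, smp, ".cov"))
    outs <- c(outs, paste0(smp, ".cov"))
    ids <- pairs$id
    for (a in 1:2) {
      keep <- ids[pairs$verdict == paste0("genome", a)]
      tab <- aggregate_counts(calls[calls$id %in% keep, ],
                              dedup = !capture,
                              sample = paste0(smp, "_allele", a))
      write_coverage(tab, pipe_path(run_dir, smp, "_allele", a, ".cov"))
      outs <- c(outs, paste0(smp, "_allele", a, ".cov"))
    }
  }
  write_manifest(run_dir, "extract", outs, list(mode = config$mode))
}

stage_diff <- function(config, run_dir) {
  smps <- pipe_samples(config)
  ins <- pipe_path(run_dir, smps, ".cov")
  require_inputs(ins, "diff", "extract")
  wt <- read_coverage(ins[1L], sample = smps[1L])
  ko <- read_coverage(ins[2L], sample = smps[2L])
  rec <- dml_test(list(wt), list(ko))
  saveRDS(rec, pipe_path(run_dir, "dml_records.rds"))
  utils::write.table(rec, pipe_path(run_dir, "dml.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tiles <- call_dmts(list(wt, ko), groups = smps, params = config$params)
  utils::write.table(tiles$dmt, pipe_path(run_dir, "dmt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(run_dir, "diff",
                 c("dml_records.rds", "dml.tsv", "dmt.tsv"),
                 list(n_sites = nrow(rec), n_dmt = nrow(tiles$dmt)))
}

stage_dmr <- function(config, run_dir) {
  ins <- pipe_path(run_dir, "dml_records.rds")
  require_inputs(ins, "dmr", "diff")
  rec <- readRDS(ins)
  # the region caller operates on sites above the mode's coverage floor
  # (5x whole-genome, 50x capture)
  rec <- rec[rec$n1 >= config$params$site_min_cov &
               rec$n2 >= config$params$site_min_cov, , drop = FALSE]
  dmrs <- call_dmrs(rec, params = config$params)
  utils::write.table(dmrs, pipe_path(run_dir, "dmrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_regions_bed(dmrs, pipe_path(run_dir, "dmrs.bed"))
  write_manifest(run_dir, "dmr", c("dmrs.tsv", "dmrs.bed"),
                 list(n_dmr = nrow(dmrs)))
}

stage_summarize <- function(config, run_dir) {
  smps <- pipe_samples(config)
  ins <- c(pipe_path(run_dir, c("genome1.fa", "genes.tsv", "cgis.bed",
                                "repeats.bed", "dmrs.tsv")),
           pipe_path(run_dir, smps, ".cov"))
  require_inputs(ins[1:4], "summarize", "simulate")
  require_inputs(ins[5L], "summarize", "dmr")
  require_inputs(ins[-(1:5)], "summarize", "extract")
  genome1 <- read_genome_fasta(ins[1L])
  ann <- gene_annotation(read_gene_table(ins[2L]),
                         cgis = read_bed_intervals(ins[3L]),
                         repeats = read_bed_intervals(ins[4L]),
                         chrom_class = genome1$class)
  dmrs <- utils::read.table(ins[5L], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  tabs <- lapply(seq_along(smps), function(i)
    read_coverage(ins[5L + i], sample = smps[i]))
  names(tabs) <- smps
  outs <- character(0); summ <- list()
  min_cov <- min(config$params$site_min_cov, 5L)
  for (smp in smps) {
    gs <- gene_summaries(tabs[[smp]], ann, genome1, min_cov = min_cov)
    utils::write.table(gs, pipe_path(run_dir, "genes_", smp, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, paste0("genes_", smp, ".tsv"))
    filt <- filter_table(tabs[[smp]], min_cov)
    summ[[smp]] <- list(
      global_mean = mean(meth_level(filt)),
      categories = as.list(methylation_categories(filt)))
  }
  targets <- identify_target_genes(dmrs, ann)
  fc <- chromosome_log2fc(filter_table(tabs[[2L]], min_cov),
                          filter_table(tabs[[1L]], min_cov))
  summary <- list(samples = summ, target_genes = targets,
                  n_target_genes = length(targets),
                  chromosome_log2fc = fc)
  jsonlite::write_json(summary, pipe_path(run_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       na = "null")
  write_manifest(run_dir, "summarize", c(outs, "summary.json"),
                 list(n_target_genes = length(targets)))
}
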