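# shared in-code fixtures; everything is generated, nothing is read from disk

# tiny deterministic genome with one CpG-rich stretch on each chromosome
tiny_genome <- function() {
  ref_genome(list(
    chr1 = "ATTCGATCGGACGTTACGTAGCCATTGGCGTTAACGCATG",
    chrX = "TTACGGATCCGTTCGATTACGGTACGCCGGTTAACGGATC"))
}

# 4-SNP table on tiny_genome covering the informativeness cases
tiny_snps <- function(genome = tiny_genome()) {
  # pos 1: T->A plain; pos 6: T->C ({C,T}, OT-blocked); pos 10: A->G
  # ({G,A}, OB-blocked); pos 17: G->C inside the CpG at 16 (in_cpg)
  snp_table(chrom = rep("chr1", 4L), pos = c(1L, 6L, 10L, 17L),
            allele1 = c("T", "T", "A", "G"),
            allele2 = c("A", "C", "G", "C"), genome = genome)
}

# small simulated world, cached per session (build once, reuse everywhere)
.world_cache <- new.env(parent = emptyenv())
small_world <- function(seed = 42L, genotype = "KO3A") {
  key <- paste0("w", seed, genotype)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- sim_config(n_autosomes = 1L, chrom_length = 60000L,
                    n_genes_per_chrom = 8L, coverage = 4,
                    genotype = genotype, seed = seed)
  world <- build_toy_genome(cfg)
  world$config <- cfg
  world$genome2 <- reconstruct_alternate_genome(world$genome, world$snps)
  world$methylome <- assign_methylome(world$annotation, world$genome, cfg)
  .world_cache[[key]] <- world
  world
}

# count table built from explicit vectors
quick_table <- function(pos, meth, unmeth, chrom = "chr1",
                        sample = "sample") {
  cpg_count_table(data.frame(chrom = chrom, pos = pos, meth = meth,
                             unmeth = unmeth), sample = sample)
}
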