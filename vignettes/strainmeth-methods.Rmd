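---
title: "strainmeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strainmeth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmeth)
```

`strainmeth` is an allele-aware whole-genome bisulfite sequencing (WGBS)
analysis toolkit with a built-in simulator. This vignette documents the
statistical models, the coordinate and chemistry conventions, and the
numerical choices, in enough detail to re-derive every computed quantity.

## Coordinates and chemistry conventions

All internal coordinates are **0-based, half-open**. 1-based conventions are
used only at file boundaries: VCF and SAM input/output and
Bismark-style `.cov` files (whose positions are 1-based and inclusive).

Bisulfite converts unmethylated cytosine to uracil (read as T); methylated
cytosine is protected. A directional paired-end library produces fragments
from the original top (OT) or original bottom (OB) strand; a PBAT-style
library produces their complements (CTOT, CTOB). In SAM output we follow the
Bismark tag convention: `XG` is the genome conversion (`CT` for top-strand
genomes, `GA` for bottom), `XR` is the read conversion, and mate 2 carries
the flipped `XR` relative to the fragment strand.

## Genome reconstruction

`reconstruct_alternate_genome()` substitutes the alternate allele of each
SNP into the reference, producing the second strain genome. Only
single-nucleotide substitutions are supported (indels in VCF input are
skipped with a message), so the two genomes share coordinates and the
operation is an exact involution: swapping `allele1`/`allele2` and
reconstructing again returns the original sequence byte-for-byte. This
round-trip is asserted in the test suite.

SNPs are annotated for allele-calling usability
(`annotate_snp_informativeness()`):

* a SNP whose two alleles are `{C, T}` is uninformative on top-strand reads
  (OT/CTOT), where bisulfite chemistry itself converts C to T;
* a `{G, A}` SNP is likewise uninformative on bottom-strand reads (OB/CTOB);
* a SNP overlapping a CpG dinucleotide in **either** genome is excluded from
  voting entirely, because its state confounds genotype with methylation.

## The simulator

The simulator is the package's ground-truth generator. Its defaults are a
frozen study condition, not tunable knobs: a diploid-like world of two
strain genomes (SNP density 1/150 bp), gene models with CpG islands (CGIs)
at 70% of promoters, a subset of Polycomb-group (PcG) target genes, repeat
intervals, and an X chromosome.

Per-CpG methylation probabilities are drawn from Beta laws per
(feature class, genotype); see `default_meth_profile()`. The wild type
background is Beta(8, 2) (mean 0.8); CGIs are Beta(1, 19) (mean 0.05). Two
knockout genotypes are modeled: `KO3A` lowers PcG promoters and bodies, and
`KO3B` lowers X-linked CGIs, X background and repeats. Effect sizes are
synthetic choices made for testability, not estimates from any dataset.

Two couplings make the truth usable for evaluation:

* **Quantile coupling**: for each site, all genotypes share one uniform
  draw pushed through their respective Beta quantile functions. Classes
  whose law is identical across genotypes therefore have *exactly* equal
  probabilities — unaffected classes are exact nulls, not approximate ones.
* **Realized truth**: read simulation records, per site, the number of
  molecules sampled (`n_frag`) and how many were methylated (`n_meth`).
  Recovery error (`evaluate_against_truth()`) is measured against this
  realized fraction (`mae_realized`), which is the quantity an extractor
  can actually recover; the Beta probability itself carries irreducible
  binomial sampling noise of order $\sqrt{p(1-p)/n}$ per site, so
  `mae_probability` is reported separately and is not a pipeline error
  measure.

Read simulation applies bisulfite conversion (rate 0.99), failed conversion
at CpGs (0.01), sequencing error (0.001), optional PCR duplicates, and
fragment lengths $\mathcal{N}(200, 20)$ with 100-bp paired reads. The
number of pairs is `round(coverage * genome_size / fragment_mean)`.
`simulate_count_tables()` is a count-level shortcut for statistics-focused
experiments: Poisson depths and beta-binomial methylated counts with
dispersion $\varphi$.

## Alignment

`align_read_pairs()` is a three-letter aligner for toy genomes: both genome
strands are C→T (and G→A) collapsed, reads are likewise collapsed, seeds of
length 20 at fixed offsets are looked up in a k-mer hash, and candidates are
verified by ungapped Hamming extension (default budget 4 mismatches per
mate, in converted space, so methylation state never affects placement).
A pair is reported only when a **unique best** location exists; ties are
returned as non-unique. The aligner intentionally has no gapped mode —
production data should be aligned externally and imported with
`read_sam()`, which accepts Bismark-style tags and infers strand from FLAGs
(with a warning) when tags are absent.

## Allele assignment

`dual_map_concordance()` keeps read pairs that map uniquely to **both**
strain genomes at the same chromosome, positions and strand — possible
because reconstruction preserves coordinates. `assign_alleles()` then votes
per overlapping SNP: a vote requires base quality ≥ 20, a position outside
the trimmed read ends, an informative SNP for the fragment strand (see
above), never a CpG-overlapping SNP, and an observed base matching one
allele. The default `strict` policy assigns a pair only when all votes
agree; `majority` requires a configurable fraction. The full vote log
(`keep_votes = TRUE`) records every considered SNP and the reason it was
used or skipped, enabling the audit that no blocked or CpG SNP ever
contributes.

## Methylation extraction

`call_methylation()` inspects, per fragment strand, the convertible
positions: C on the top strand (reported at the C of the CpG) and G on the
bottom strand (reported at the same C, i.e. position − 1 of the G).
Defaults: mate-overlap regions are counted once (mate 1 wins), reads are
end-trimmed (10 bp 5′, 5 bp 3′ per mate) before calling, duplicates are
collapsed by (chrom, start1, start2, strand), and sites destroyed by a SNP
in either genome (`snp_destroyed_cpgs()`) are excluded. Increasing trim
windows can only remove calls, never add them — a monotonicity property
asserted in the tests. Capture-style data uses
`strand_restrict = "original_bottom_only"` and no deduplication.

## Differential methylation

`dml_test()` is a two-group beta-binomial Wald test. With group mean
$\hat\mu = \sum k_i / \sum n_i$ and dispersion $\varphi$,

$$\widehat{\mathrm{Var}}(\hat\mu) =
  \frac{\sum_i n_i\,\hat\mu(1-\hat\mu)\,\bigl(1+(n_i-1)\varphi\bigr)}
       {\bigl(\sum_i n_i\bigr)^2},$$

and $z = (\hat\mu_1 - \hat\mu_2)/\sqrt{v_1 + v_2}$ with a two-sided normal
p-value. When the difference and both variances are zero, $z = 0$ and
$p = 1$ by convention. The statistic is exactly antisymmetric under group
swap.

Dispersion is estimated per site by method of moments from the replicate
$X^2$ statistic, $\tilde\varphi = (X^2/(m-1) - 1)/(\bar n - 1)$, then
shrunk halfway toward the genome-wide mean:
$\hat\varphi = 0.5\max(\tilde\varphi,0) + 0.5\max(0,\overline{\tilde\varphi})$.
The mean (not median) is the shrinkage anchor because the raw
moment estimates are heavily zero-inflated at typical depths: the median is
often exactly 0, which would remove the shrinkage protection entirely.
Single-replicate groups have no replicate variance, so dispersion is
borrowed from a local window (`smooth_span`, default ±500 bp, computed with
cumulative sums) treating neighboring sites as pseudo-replicates;
`smooth_span = 0` falls back to binomial variances.

Multiple testing uses Benjamini–Hochberg (`bh_fdr()`, a thin wrapper over
`p.adjust`).

Two calling modes:

* **DMTs** (`call_dmts()`): non-overlapping 1-kb tiles; a tile is eligible
  when its pooled coverage is ≥ 10 in **every** sample; called when
  FDR < 0.01 **and** |difference| > 0.4. The difference gate is hard —
  a planted 0.3 difference is never called regardless of significance.
* **DMRs** (`call_dmrs()`): runs of seed sites ($p < 10^{-5}$, consistent
  direction) merged across gaps ≤ 100 bp, then filtered to ≥ 10 CpGs,
  ≥ 50 bp, ≥ 50% of member sites significant, and mean |difference| ≥ 0.2;
  adjacent same-direction regions are merged. Records must be
  position-sorted (a contract error otherwise).

Descriptive summaries: `methylation_categories()` bins site levels into
hyper (> 0.8), intermediate (0.2–0.8 inclusive) and hypo (< 0.2);
`chromosome_log2fc()` computes per-chromosome log2 ratios of mean
methylation over shared sites (exactly 0 for a sample against itself).

## Feature summaries

`gene_summaries()` reports the unweighted site-mean methylation of the TSS
window (TSS ± 1 kb, strand-aware, clipped at chromosome ends with a
warning) and gene body. `identify_target_genes()` intersects DMRs of a
chosen direction with gene footprints extended by the promoter flank on the
TSS side only. `cgi_split()` partitions filtered site-level methylation
into CGI and non-CGI vectors, optionally restricted to one chromosome
class, feeding `compare_groups()`: exact Mann–Whitney U via `pwilcox` when
$n_A n_B \le 10^4$ and there are no ties, exact signed-rank via `psignrank`
for $n \le 25$, Kolmogorov–Smirnov via `ks.test`; two-sided p-values are
twice the smaller tail, capped at 1; zero differences in the paired test
are dropped with a warning.

## Pipeline

`run_stage()` executes the staged pipeline (simulate → reconstruct → align
→ split → extract → diff → dmr → summarize) in a run directory, writing a
JSON manifest per stage; a missing prerequisite produces an error naming
the missing file and the stage that creates it. `pipeline_config()` freezes
the study conditions; `mode = "capture"` switches to
original-bottom-strand-only extraction without deduplication and raises the
site coverage floor from 5× to 50×.

## Problem sizes

The package targets toy genomes (≤ ~10 Mb; the internal aligner warns
beyond that). Default simulation worlds (two 300-kb autosomes plus a 300-kb
X) are a deliberate package-level choice: large enough for ~20,000 CpGs,
dozens of genes and stable statistics, small enough that the full test
suite and an end-to-end pipeline run complete in minutes on one core.

## Worked example

```{r example}
cfg <- sim_config(n_autosomes = 1L, chrom_length = 60000L,
                  n_genes_per_chrom = 8L, genotype = "KO3A", seed = 42L)
world <- build_toy_genome(cfg)
meth <- assign_methylome(world$annotation, world$genome, cfg)
wt <- simulate_count_tables(meth, "WT",   coverage = 50, phi = 0.02,
                            n_rep = 2L, seed = 1L)
ko <- simulate_count_tables(meth, "KO3A", coverage = 50, phi = 0.02,
                            n_rep = 2L, seed = 2L)
rec <- dml_test(wt, ko)
dmrs <- call_dmrs(rec)
head(dmrs)
identify_target_genes(dmrs, world$annotation)
```
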