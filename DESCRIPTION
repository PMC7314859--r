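Package: strainmeth
Title: Allele-Aware Bisulfite Methylome Analysis for Hybrid Strain Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific whole-genome and capture bisulfite
    sequencing analysis in inter-strain hybrids: reconstruction of an
    alternate strain genome from a biallelic SNP table, three-letter
    bisulfite alignment of paired-end reads with a dual-genome concordance
    filter, conversion-aware assignment of read pairs to parental alleles,
    per-CpG methylation extraction with read-end trimming, a two-group
    beta-binomial Wald test with tile (DMT) and region (DMR) calling, and
    feature-level summaries (promoter/gene-body means, CpG-island splits,
    target-gene identification). A fully seeded simulator generates diploid
    toy genomes, genotype-dependent methylomes (wild type and de novo
    methyltransferase knockouts) and paired bisulfite reads with complete
    truth labels, so that every stage is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
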