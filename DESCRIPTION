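Package: hapscan
Title: Fast Linear Mixed Model Association Scans for SNPs, Haplotype
    Alleles and Haplotype Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association scans for homozygous inbred-line panels
    in which the tested genetic unit may be a single SNP, a haplotype-allele
    carrier indicator, or a multi-allele haplotype block. A single spectral
    decomposition of the marker-derived kinship matrix turns the linear mixed
    model into a weighted regression, the polygenic heritability is profiled
    per tested unit by a one-dimensional likelihood search, and a two-pass
    EMMAX-style screen keeps the whole scan within one to two genome-wide
    regression rounds. Includes Four-Gamete-Test haplotype block construction,
    rare-allele merging, Bonferroni thresholds, genomic-control diagnostics,
    and a simulator of LD-structured inbred genotypes and polygenic plus QTL
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
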