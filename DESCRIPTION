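Package: alleledrift
Title: Loss of Heterozygosity and Allele-Specific Expression from Paired
    Exome and Transcriptome Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects loss of heterozygosity (LOH) and allele-specific
    expression (ASE) in a tumor/normal pair from per-locus allele-count
    tables.  High-confidence single nucleotide variants are filtered and
    genotyped from DNA counts, LOH loci are called with a one-sided
    cumulative binomial homozygosity test against the normal heterozygous
    loci, and biased allelic expression is called from RNA counts with a
    copy-number-adjusted binomial test (the null success probability taken
    from the exome variant allele frequency rather than a fixed 0.5),
    an allele drift-ratio band, and family-wise multiple-testing
    correction over the loci that pass the RNA coverage gate.  Includes
    gene-level aggregation, cross-sample comparison of preferred alleles,
    a synthetic tumor/normal exome + transcriptome generator with ground
    truth for end-to-end validation, readers for TSV/VCF allele counts and
    BED12/GFF3 gene models, and a pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    withr
Config/testthat/edition: 3
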