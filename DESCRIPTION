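Package: capvar
Title: SNV Calling and Haplotype-Based Copy Number Estimation for
    Copy-Number-Variable Targeted Capture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for assessing single nucleotide variation
    and copy number in highly copy-number-variable target regions sequenced
    by targeted capture and long-read pyrosequencing. Detects candidate SNVs
    from read pileups with a strand-aware minimum-evidence rule, filters them
    with a pooled binomial sequencing-error model, masks paralogous regions,
    classifies calls into genotype classes by variant allele frequency bands
    for arbitrary diploid copy number, annotates known versus putative novel
    variants, phases read-backed haplotypes over dense SNV windows, estimates
    diploid copy number from integer haplotype read ratios, and evaluates
    genotype concordance against reference genotypes. A built-in synthetic
    read generator with a controlled substitution-error process makes every
    stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
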