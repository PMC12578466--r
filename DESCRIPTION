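Package: meioscan
Title: Crossover and Copy-Number Detection in Allopolyploid Hybrid Gamete
    Populations from SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homologous meiotic crossovers, putative non-homologous
    (homoeologous A-C) recombination events and chromosome copy-number
    variation in Brassica interspecific-hybrid gamete-derived populations
    genotyped on Infinium-style SNP arrays. Genotype calls are filtered
    per cross-combination, recoded to parental-origin symbols, smoothed by
    iterated run-length replacement and scanned for breakpoints; logR and
    B-allele-frequency signals are segmented by binary segmentation and
    classified into deletions and duplications; crossover landscapes are
    summarised in 1 Mb windows and relative to centromeres, with chi-square,
    one-way ANOVA and LSD comparisons across genotype combinations. A
    synthetic allopolyploid-meiosis simulator (reduced and first-division-
    restitution unreduced gametes, homoeologous exchanges, aneuploidy, array
    noise) provides full ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
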