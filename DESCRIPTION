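Package: popdiffr
Title: Population Differentiation, Derived-Allele and Combined-Population
    eQTL Analysis with a Forward Wright-Fisher Neutral Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Region-based analysis of recent population differentiation from
    phased genotypes. Implements the Hudson two-population F_ST estimator with
    sample-size bias correction and ratio-of-averages aggregation over fixed
    windows, genes and annotation classes; a nine-priority gene-component
    partition of the genome (CDS, UTRs, noncoding exons, introns and flanking
    regions) with repeat classification; derived-allele-frequency (DAF) and
    delta-DAF statistics with fixed-size ranked grouping; a combined-population
    cis/trans eQTL scan using a linear model with a population covariate and
    separate Benjamini-Hochberg control per family; pairwise linkage
    disequilibrium (D' and r squared) from phased haplotypes; a forward
    Wright-Fisher simulator of a split demography (burn-in, split into two
    demes, linear growth, stationary drift) as the neutral reference for
    windowed F_ST distributions; and a seeded synthetic-data generator that
    emits all pipeline input formats with planted effects and truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    Rcpp,
    BiocGenerics,
    IRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
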