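Package: sjusage
Title: Splice-Junction Differential Usage and Mouse Cross Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Splice-junction-based differential usage analysis for bulk
    RNA-seq of mouse embryos: reads STAR SJ.out.tab junction count tables,
    filters expressed genes and junctions, groups junctions into shared
    donor/acceptor anchor sets, tests per-junction usage between genotype
    groups with a dual p-value/effect-size rule and optional FDR control,
    and computes the percent-spliced-in (PSI) statistic for cassette exons
    from inclusion and skipping junction reads. Companion utilities score
    Mendelian segregation ratios with chi-square goodness-of-fit tests,
    summarise pre-implantation embryo culture trajectories on an ordinal
    blastocyst ladder, and simulate junction counts with litter batch
    effects, genetic crosses with stage-specific lethality, and culture
    cohorts, so that every analysis step is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
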