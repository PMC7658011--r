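Package: symbiotrend
Title: Trend Detection and Colonization Phenotyping for Grass-Endophyte
    Seed Maintenance Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analyses for tracking co-adaptation in
    grass-endophyte symbioses across generations of a seed maintenance
    program. Detects genes with strictly monotone expression trends
    across ordered generations using a combinatorial chance null, an
    excess z-test and exact count confidence intervals; normalizes
    dual-organism (host plus fungal symbiont) RNA-seq count matrices
    and partitions read shares by organism; quantifies fungal
    colonization from microscopy section morphometry (hyphal counts,
    diameters, biovolume index) with rank and contingency tests;
    estimates seed-transmission rates with exact binomial intervals;
    and simulates all required inputs (negative-binomial count matrices
    with planted trends, section morphometry, a selective
    open-pollination transmission program, tillering time series) so
    every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
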