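Package: meiohot
Title: Stage-Resolved Epigenomic Dynamics of Meiotic Recombination Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stage-comparative analysis of histone-mark ChIP-seq
    peaks and NOMe-seq chromatin accessibility across mouse meiotic prophase I.
    Classifies DSB-hotspot-associated H3K4me3 peaks into temporal turnover
    classes (early-forming, fast-turnover, slow-turnover, persistent) from
    their presence across ordered stages, calls nucleosome-depleted regions
    from GCH methylation with a sliding-window chi-squared test, detects
    H3K9me2 dips at hotspots, builds spike-in-normalized binned coverage
    tracks and region-anchored signal matrices, and ships a seeded synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
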