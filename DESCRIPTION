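Package: epiprotect
Title: Epigenetic Protection of H3K27me3 Target Genes Against Promoter
    Hyper-Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mean-field and stochastic single-cell models of coupled
    promoter histone methylation (H3K4me3/H3K27me3), promoter DNA
    methylation and transcription, with fixed-point and bifurcation
    analysis, quasi-steady-state population simulation, and a DNA-repair
    protocol that estimates promoter hyper-methylation probabilities.
    Includes a genomic stage that assigns genes 0/1 histone-state
    quadruplets from peak intervals, derives stress-responsive gene sets,
    characterises promoter CpG density, and generates fully synthetic
    peak/annotation/sequence fixtures with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
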