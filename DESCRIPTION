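Package: panelpopgen
Title: Population Structure and Linkage Disequilibrium for Inbred SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-genetic analysis of biallelic SNP genotype panels of
    (mostly) inbred lines on a genetic map, as used in crop diversity panels:
    readers and quality/MAF filtering for a tab-separated panel format and
    VCF; per-population diversity statistics (polymorphism information
    content, minor-allele-frequency spectra); haploid Weir-Cockerham F_ST
    with a sliding-window differentiation scan against a bootstrap null and
    hierarchical variance components; a linkage-disequilibrium suite
    (r-squared, D-prime with likelihood confidence bounds, exact-test
    significance with Benjamini-Hochberg FDR, loess decay curves, background
    LD, Gabriel-style haplotype blocks); and a Balding-Nichols /
    founder-mosaic simulator of structured panels with known truth so every
    stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
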