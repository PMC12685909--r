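Package: hostshift
Title: Analysis of Experimental Phage Host-Range Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of bacteriophage host-shift evolution
    experiments. Implements the reduction-in-bacterial-growth (RBG)
    virulence statistic from plate-reader optical densities, virulence-gain
    testing with Welch's t-tests and sequential Bonferroni (Holm)
    correction, one-way ANOVA with Tukey's HSD for final phage titers,
    patristic-distance summaries of genetic distance to a phage's native
    host range on a strain phylogeny, strand-aware mapping of genomic
    variants to transcript coordinates, and a synthetic-data generator
    that emulates the serial-passage cross-infection design for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
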