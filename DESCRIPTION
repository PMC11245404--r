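Package: circpep
Title: Discovery of Protein-Coding Circular RNAs from Ribosome Profiling
    and Proteogenomic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for calling translated circular RNAs
    (circRNAs) and characterising their encoded microproteins. Builds
    mature circular sequences from exon models, predicts junction-spanning
    open reading frames on pseudo-circularised (4x replicated) sequences,
    matches ribosome footprints to back-splice junction windows with
    overhang accounting, applies target-decoy false discovery rate control
    to junction-spanning peptide identifications, computes physicochemical
    profiles (molecular weight, isoelectric point, instability index,
    GRAVY) of candidate circRNA-encoded proteins, and derives the
    translation ratio statistic. Includes a seeded synthetic-data
    generator with ground truth so every stage of the pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
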