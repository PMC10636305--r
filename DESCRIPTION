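Package: trichrom
Title: Multi-Enzyme Chromatin Conformation Capture Analysis at 100 bp
    Resolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for triple-digest chromatin conformation
    capture (4C and Hi-C) experiments analysed at 100 bp resolution.
    Provides in silico multi-enzyme restriction digestion of genomes,
    ligation-contact tables with sonication-end UMI deduplication,
    viewpoint interaction profiles with Poisson local-background loop
    calling, differential and allele-specific loop tests, binned contact
    matrices with virtual 4C, distal-interactivity hotspot calling,
    insulation scores, aggregate peak analysis, stripe-residual
    decomposition and loop-asymmetry quantification, plus a seeded
    ligation-library simulator that supplies ground truth for every
    caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
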