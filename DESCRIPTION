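Package: hingehic
Title: Hi-C Contact Maps, Insulation Boundaries, Hinge-Like Flares, and
    Enhancer Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for cis Hi-C contact data in early-development
    and gamete chromatin studies. Builds per-chromosome binned contact
    matrices from 4DN-style valid-pairs files, balances them by iterative
    correction, and derives observed/expected ratios, contact-decay curves,
    multi-window diamond insulation scores, TAD boundary calls, and A/B
    compartment assignments from the first principal component of the
    observed/expected correlation matrix. Implements a caller for
    anti-diagonal "flare" (hinge-like domain) features from positive
    insulation runs with width, periodicity, and pivot-symmetry statistics;
    ROSE-style enhancer stitching, ranking, super-enhancer cutoff and group
    stratification with insulation-composition tables; a valid-pairs mixing
    simulator quantifying boundary detectability under contamination; and a
    seeded synthetic valid-pairs generator with known ground truth (contact
    decay, TADs, compartments, hinge flares, graded enhancer signal).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
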