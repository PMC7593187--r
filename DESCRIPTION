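Package: refugia
Title: Phylogeography and Climate-Change Risk for Cold-Adapted Mountain Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Combined mtDNA phylogeography and species-distribution-modeling
    workflow for range-restricted cold-adapted species. Collapses aligned COI
    sequences into haplotypes and computes Nei haplotype and nucleotide
    diversity, AMOVA phi with a permutation null, and a minimum-spanning
    haplotype network; builds extreme-cell climate features on a coarse
    occupancy lattice, samples buffered pseudo-absences, fits an ROC-gated
    ensemble suitability model, hindcasts through millennial paleoclimate
    anomaly slices with ice-sheet clipping to derive a climate-stability
    refugium surface, and projects future scenarios to a per-region
    haplotype-risk statistic. Ships a fully deterministic synthetic-world
    generator with exposed ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    igraph,
    jsonlite,
    mgcv,
    pracma,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
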