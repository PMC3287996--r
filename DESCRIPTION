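Package: footprintr
Title: Phylogenetic Footprinting of Mammalian Promoters and Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate regulatory regions (promoters and
    enhancers) upstream of a gene by phylogenetic footprinting across
    mammalian species. Provides ATG-anchored sequence input/output,
    seed-and-extend gapped local alignment with Karlin-Altschul
    E-values, conserved-region calling by identity/length/species-support
    rules, UPGMA-guided progressive multiple alignment of orthologous
    regions, position-weight-matrix scanning with a randomization-based
    motif over-representation statistic, cross-species motif-conservation
    filtering, wild-type/mutant binding-site loss checks, and a
    phylogeny-aware sequence-evolution simulator with planted conserved
    elements and motif instances for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
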