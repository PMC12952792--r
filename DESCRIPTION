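Package: poreseg
Title: Segmentation and m6A Calling for Nanopore Direct-RNA Raw Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments nanopore direct-RNA raw current traces into alternating
    base and transition blocks with a hierarchical hidden Markov model built on
    a jiggling-translocation model of motor-protein dynamics, aligns the block
    means to reference k-mer lists with a many-to-one dynamic program, and
    calls N6-methyladenosine at the site and single-molecule level with
    fixed-mean two-component Gaussian mixtures. Includes poly(A)-tail signal
    standardization, k-mer pore-model table handling, eventalign-style export,
    segmentation benchmark metrics, a ground-truth signal simulator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
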