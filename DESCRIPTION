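Package: songDelim
Title: Acoustic and Molecular Species Delimitation for Island Crickets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for delimiting cricket species from
    calling songs and DNA sequence divergence, with island-biogeographic
    interpretation. Extracts song measurements (fundamental frequency,
    syllabic pattern, syllable and sentence periods, pulse rate) from
    recordings, standardizes them to a common temperature with linear
    standard curves, classifies song types by K-means, applies a
    minimum-divergence threshold rule over uncorrected p-distances to flag
    candidate species, classifies archipelago species as immigrant,
    anagenetic or cladogenetic on a labelled phylogeny (including Fitch
    parsimony counts of host-association shifts), and fits logistic
    species-discovery curves to survey effort data. Ships seeded synthetic
    generators (songs, Jukes-Cantor alignments, feature tables, survey
    histories) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    minpack.lm,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
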