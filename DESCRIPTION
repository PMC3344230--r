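Package: reticulator
Title: Reticulate-Origin Inference for Apogamous Fern Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-evidence reconstruction of reticulate (hybrid and
    polyploid) origins in apogamous fern species complexes such as the
    Pteris cadieri complex. Provides flow-cytometric ploidy calling against
    an internal calibration standard, spore-count reproduction typing,
    clone-based nuclear allele calling with dosage-ambiguous genotype
    inference, simple indel coding of alignment gaps, a compact maximum
    parsimony engine (Fitch lengths, CI/RI, exhaustive and heuristic
    searches, nonparametric bootstrap, ILD permutation test), chloroplast
    haplotype grouping, allele-to-haplotype maternal mapping, and a
    diploids-first minimal-presumed-taxa reticulate network search,
    together with a synthetic hybrid-complex data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
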