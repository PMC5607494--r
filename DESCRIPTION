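Package: hmdnuc
Title: Nucleosome Organization and Sequence Preference in Hypomethylated Domains
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nucleosome organization in hypomethylated
    domains (HMDs) of vertebrate genomes. Segments a CpG methylome into HMDs,
    detects accessible nucleosome linkers from cut-count data, builds
    boundary-anchored metaprofiles, estimates nucleosome spacing by
    autocorrelation, trains linear k-mer spectrum support vector machines to
    predict linker positions and HMDs from sequence, analyses motif
    periodicity, and computes equilibrium hard-rod nucleosome occupancy from a
    sequence-dependent energy model. Ships a synthetic chromatin generator
    with ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
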