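Package: clonesweep
Title: Clonal Architecture and Selective-Sweep Dynamics from Bulk Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the clonal architecture of bulk-sequenced tumors and the
    strength of subclonal selection acting on driver mutations. Converts
    variant-allele fractions to cancer cell fractions using sample purity and
    local copy number, estimates variant multiplicity and the phylogenetic
    order of mutation versus copy gain, models driver and hitch-hiker allele
    trajectories during selective sweeps, fits a per-tumor selection
    coefficient from passenger frequency spectra, summarizes intratumor
    heterogeneity with a binned Shannon diversity index and clone-tree
    linearity/branching indices, and scores up/down gene-expression signatures
    with an information-coefficient association test. Ships a synthetic tumor
    generator so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
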