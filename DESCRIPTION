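Package: cycloscreen
Title: LC-MS Screening and Chemotaxonomy of Cyclotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for large-scale liquid chromatography-mass
    spectrometry (LC-MS) screening of cyclotides, the head-to-tail cyclic
    cystine-knot peptides of the Violaceae. Provides mass chemistry for
    cyclic and linear peptides (monoisotopic and average masses, disulfide
    accounting, modification deltas, m/z conversion), charge-state
    deconvolution of per-sample feature tables into neutral-mass
    observations, mass- and retention-time-window calling of cyclotide
    candidates, hexose glycoform ladder annotation, cross-sample
    deduplication into a cyclotide registry, in-silico GluC/trypsin
    digestion with b/y fragment ladders for MS/MS sequence confirmation,
    presence/absence chemotaxonomic clustering (UPGMA and neighbor
    joining), diversity extrapolation, and a fully parameterized synthetic
    screen generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
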