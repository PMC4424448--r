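Package: dera
Title: Sample-Specific Regulation Networks and Core Regulation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentially Expressed Regulation Analysis (DERA) infers
    sample-specific gene regulation networks by discretizing each tumor
    sample's expression into a ternary over/unchanged/under indicator
    relative to a reference sample set, overlaying the indicators on a
    prior signed regulatory network, and retaining only regulations whose
    endpoint states are consistent with the edge sign (activation: same
    sign; inhibition: opposite signs). Regulation instances shared
    identically by at least a threshold fraction T of a phenotype group
    form its core regulation set, which is decomposed into connected
    subnetworks, compared between groups, and validated across cohorts.
    Includes a synthetic cohort generator with planted sign-consistent
    regulations at controlled prevalence for ground-truth recovery tests,
    readers and writers for SIF-style signed edge lists and tab-separated
    expression matrices, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
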