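Package: rnamason
Title: RNA 3D Model Assembly from Secondary-Structure Motifs with SAXS Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assembles coarse-grained RNA 3D models from a library of
    structural fragments while preserving a user-provided secondary
    structure. The secondary structure is compiled into a motif graph
    (stems, loops, single strands); pseudoknots are removed by an exact
    dynamic program that maximizes the number of nested base pairs and are
    re-applied as tertiary-contact restraints. Starting models are built by
    leaf-first beam search over fragment choices minimizing glycosidic
    nitrogen clashes, then refined by replica-exchange Monte Carlo under a
    knowledge-based distance potential, flat-bottom contact restraints, and
    an optional small-angle X-ray scattering (SAXS) goodness-of-fit
    restraint computed with the Debye formula.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
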