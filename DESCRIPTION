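Package: cytoscatter
Title: Label-Free Single-Cell Phenotyping from Light-Scattering Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inversion of small-angle light-scattering
    profiles (LSPs) of single cells modelled as concentric core-shell
    (nucleus-cytoplasm) spheres, using the Aden-Kerker extension of Mie
    theory. Provides lookup-table retrieval of four biophysical properties
    (diameter, nucleus/cytoplasm ratio, nuclear and cytoplasmic refractive
    index), a synthetic population generator for monocyte and macrophage
    (M0/M1/M2) phenotypes, a viscoelastic microfluidic alignment criterion,
    and supervised classification (SVM, k-nearest-neighbour, decision tree)
    with repeated stratified cross-validation, confusion statistics and
    one-way ANOVA with Tukey post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    rpart,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
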