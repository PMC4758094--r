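Package: oplstep
Title: Stepwise OPLS-DA Modelling of Developmental Proteomics Gradients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein expression gradients across ordered
    developmental zones, such as the phloem-cambium-xylem series of
    wood formation. Implements top-3 peptide protein quantification with
    tissue normalisation and section pooling, column-centred principal
    component analysis, orthogonal projections to latent structures
    discriminant analysis (OPLS-DA) fitted between consecutive zones,
    transition effect profiles (predictive loadings weighted by the
    score-vector norm), a meta-PCA overview of all transitions,
    jack-knife confidence intervals for up/down/no-change calls, and a
    seeded synthetic-data generator emulating a pooled tangential-section
    sampling design with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
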