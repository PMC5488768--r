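Package: poeBLUP
Title: Parent-of-Origin-Effect Mixed Models for Pedigreed Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component estimation and BLUP for genomic-imprinting
    (parent-of-origin) analyses in pedigreed livestock populations. Implements
    the two-genetic-effects imprinting animal model with transmitting
    abilities as sire and as dam, an equivalent reparameterisation that yields
    imprinting effects and their prediction error variances directly from the
    mixed model equations, the animal-model null, AI/EM REML with
    Mendelian-sampling residual weighting for reduced (parents-only) data,
    a REML likelihood-ratio test for imprinting variance, reliabilities and
    genetic trends, a penalised quasi-likelihood logit variant for binary
    carcass grades, and a gene-dropping simulator with the exact covariance
    structure the models assume. Pedigree utilities cover inbreeding
    (Meuwissen-Luo), the sparse inverse numerator relationship matrix with
    Westell-Van Vleck phantom-parent genetic groups, and pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Matrix, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
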