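Package: kinblend
Title: Blended Pedigree-Genomic Kinship Matrices for BLUP Prediction
Version: 0.1.0
Authors@R:
    person("Pergamino", "Biometrics", email = "biometrics@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic prediction of breeding values in structured
    breeding populations using weighted combinations of pedigree and genomic
    relationship matrices. Builds the numerator relationship matrix A from a
    pedigree by the tabular method, the VanRaden method-1 genomic matrix G
    from SNP dosages, a rescaled matrix Gs compatible with the pedigree base,
    and the blended kinship K = w*A + (1-w)*Gs. Fits single-kernel (A-BLUP,
    G-BLUP, K-BLUP) and two-kernel (AG-BLUP) linear mixed models by REML with
    known heteroscedastic residual weights, sweeps the blending weight under
    family-structured cross-validation (within-family and among-family
    schemes), and evaluates predictive ability, empirical bias and MSEP,
    including the Hotelling-Williams test for dependent correlations. A
    gene-dropping simulator generates synthetic multi-generation breeding
    populations with full-sib family structure for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
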