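Package: twinfiber
Title: Longitudinal Twin Analysis of White Matter Volume and Microstructure
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for longitudinal twin studies of white matter
    development: diffusion tensor estimation and scalar maps (fractional
    anisotropy, axial and radial diffusivity), deterministic FACT streamline
    tractography with group average-fiber construction and along-tract
    summaries, deformation-based morphometry via Jacobian determinants with
    Benjamini-Hochberg FDR control, pure-white-matter masking and FA histogram
    comparisons, cohort statistics with family-adjusted degrees of freedom,
    and maximum-likelihood twin variance-component models (AE/ACE, univariate
    and bivariate Cholesky) with heritability, genetic/environmental
    correlations and profile-likelihood confidence intervals. A synthetic-data
    module generates twin cohorts, diffusion phantoms and deformation fields
    with known ground truth so every stage can be verified without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
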