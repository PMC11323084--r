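Package: rdpscore
Title: Ramachandran Density Deviation Scoring for Missense Variant
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-residue backbone dihedral (phi, psi) ensembles,
    such as those produced by molecular dynamics trajectory post-processing,
    into Ramachandran density grids by two-dimensional Gaussian kernel
    density estimation, scores each variant ensemble by the fraction of
    grid points whose density deviates from a benign/wildtype baseline
    beyond its per-point standard deviation, and classifies missense
    variants as deleterious or non-deleterious against a threshold
    calibrated from log-normal fits of known benign and pathogenic score
    distributions. Includes a reader for the GROMACS 'gmx rama' text
    dialect, trajectory windowing and subsampling utilities, a
    germline/somatic variant-table overlap module, and a synthetic
    dihedral-ensemble simulator with named Ramachandran basins for
    testing the full pipeline without running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
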