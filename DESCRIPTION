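Package: tightropekit
Title: Single-Molecule and Biochemical Analysis of Glycosylase Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule DNA tightrope and bulk
    biochemistry studies of DNA-repair protein turnover. Converts per-frame
    particle positions into mean squared displacement curves, diffusion
    coefficients and anomalous diffusion exponents; estimates bound-state
    half-lives from right-censored dwell times by survival analysis;
    quantifies two-colour colocalization; calibrates atomic force microscopy
    particle volumes against molecular weight and deconvolves species
    mixtures; and fits pre-steady-state burst kinetics and ligand-depletion
    (quadratic) binding isotherms. A synthetic-data generator with known
    ground truth emulates every observable so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
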