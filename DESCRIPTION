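Package: cmcssr
Title: Canonical Microcircuit Modelling of Steady-State MEG Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Neurophysiologically-informed spectral analysis of single-source
    MEG virtual-sensor recordings. Implements a four-population canonical
    microcircuit (spiny stellate, superficial pyramidal, inhibitory
    interneuron, deep pyramidal) neural mass model, predicts 1-100 Hz power
    spectra through the linearised transfer function, and estimates synaptic
    gains and time constants by variational-Laplace Bayesian inversion.
    Includes the spectral front end (smoothed periodogram, robust 1/f
    pre-whitening, cohort unit-area normalisation, band peak extraction), a
    perturbation-based contribution analysis of the synaptic parameters,
    cohort and pharmacology group statistics (spectral covariance maps,
    Bonferroni-corrected parameter-feature correlations, repeated-measures
    ANOVA with Greenhouse-Geisser correction), and ground-truth synthetic
    data generators for cohort and drug-crossover designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
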