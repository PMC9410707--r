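Package: alphadec
Title: Periodic and Aperiodic Decomposition of Developmental EEG Alpha Activity
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for decomposing resting-state EEG power spectra into periodic
    (oscillatory) and aperiodic (1/f-like) components and for studying how alpha-band
    parameters evolve during brain maturation. Implements Welch spectral estimation
    with amplitude-based epoch rejection, an iterative spectral parameterization
    algorithm (robust aperiodic fit plus Gaussian peak extraction), extraction of
    individual alpha frequency and total, relative and aperiodic-adjusted alpha power,
    parieto-occipital cluster aggregation with fit-quality fallback, effective-number-
    of-tests multiplicity correction, Gelman-scaled regression models with an optional
    Bayesian backend supporting sequential prior updating, a calibrated synthetic
    cohort generator, and confound simulations contrasting relative and
    aperiodic-adjusted band power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    minpack.lm,
    jsonlite,
    optparse
Config/testthat/edition: 3
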