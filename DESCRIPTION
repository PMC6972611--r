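Package: llpsnmr
Title: NMR Analysis of Liquid-Liquid Phase Separation Preceding
    Crystallization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to characterize a dense liquid precursor phase in the
    aqueous crystallization of a weak-acid drug (ibuprofen as the model
    compound). Locates the binodal and spinodal limits of the
    liquid-liquid miscibility gap from 1H NMR peak-integral partitioning,
    fits pulsed-field-gradient stimulated-echo (PFG-STE) decays for
    per-phase translational diffusion coefficients, inverts T1/T2 ratios
    into rotational correlation times via the like-spin dipolar spectral
    densities, calibrates NOESY cross-peak intensities into interproton
    distances through the r^-6 relation, and models weak-acid protolysis
    speciation along a potentiometric titration. A synthetic-data
    generator emulates the full measurement chain so every estimator is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
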