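Package: fibrilslit
Title: Kinked-Fibril Morphology and Slit-Confinement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative modelling and single-fibril statistics for kinked
    semiflexible nanofibrils (such as TEMPO-oxidised cellulose nanofibrils)
    under weak slit confinement. Provides a coarse-grained generator of
    fibril backbones as 2D polylines with kinks of given turning angle and
    bend-direction persistence; a geometry-based accept/reject simulator of
    adsorption into a rectangular slit, with the rigid-rod closed-form
    cross-check; and the morphology statistics used in AFM single-molecule
    studies: kink detection on traced backbones, the nematic order parameter
    S2D and orientation distributions, radius of gyration of resampled
    contours, kink densities and segment lengths, Markov sign statistics of
    bend directions with exact enumeration theory, Onsager excluded-area
    estimates, and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
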