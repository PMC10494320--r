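Package: paleokit
Title: Quantitative Toolkit for Paleosite Chronology, Paleoecology and Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the quantitative analyses that anchor a
    multi-proxy Miocene paleosite study: authigenic 10Be/9Be depositional dating
    under scenario-based initial-ratio models, two-nuclide 26Al/10Be burial-duration
    modelling with pre-burial steady-state denudation and post-burial muogenic
    production, pedogenic-carbonate stable-isotope summaries with the paleo-shade
    woody-cover proxy, 2D outline morphometrics (Moore-neighbour tracing,
    equidistant semilandmarks, generalized Procrustes analysis, elliptical Fourier
    transforms, PCA and cross-validated linear discriminant classification), 3D
    sliding-semilandmark superimposition, log-log allometric body-mass estimation
    with detransformation bias correction, and posterior-tree summarization
    (burn-in, clade frequencies, maximum-clade-credibility trees, highest posterior
    density intervals, effective sample sizes). Seeded synthetic-data generators
    provide ground-truth inputs for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    phangorn,
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
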