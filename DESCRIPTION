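Package: liquidperc
Title: Midlevel Shape Features and the Perception of Liquid Viscosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the visual
    system estimates liquid viscosity from midlevel shape and motion
    features. Generates synthetic liquid stimuli (a viscosity-controlled
    height-field simulator with mesh export and silhouette rendering) and
    simulated observer rating tables with known latent structure; measures
    bespoke 3D mesh statistics (shape-index-weighted curvature, surface
    flatness, center-of-mass height, total absolute Gaussian curvature),
    2D silhouette shape statistics and dense pyramidal Lucas-Kanade optical
    flow; and fits the core perceptual model: Horn's parallel analysis to
    choose the factor count, maximum-likelihood factor analysis of feature
    ratings, Harman factor scores, and a linear regression predicting
    perceived viscosity from the factors, with frozen-model transfer across
    scene contexts, representational dissimilarity analysis, and pixel- vs
    feature-space principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
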