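Package: lucent
Title: Layer-Wise Latent Probing of Translucency Perception
Version: 0.1.0
Authors@R:
    person("Lucent", "Maintainers", email = "maintainers@lucent.dev",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic replication pipeline for studying
    how translucent material appearance is represented in the layer-wise
    latent space of a style-based image generator.  Provides a procedural
    renderer for soap-like translucent stimuli with known generative factors,
    an analytic multi-scale generator whose coarse/middle/fine latent layers
    control shape, material and body color, layer-subset latent morphing,
    per-layer linear decision-boundary probing with normalized-distance
    translucency predictions, boundary-normal appearance editing, ICA-based
    discovery of translucency-diagnostic chromatic kernels, and simulation
    plus analysis of three psychophysical experiments (real-versus-generated
    discrimination, attribute rating, and forced-choice attribute selection
    over morph sequences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
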