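Package: strokemap
Title: Mollweide Flattening of Diffusion MRI and Stroke Territory Recognition
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flattens three-dimensional diffusion-weighted MRI brain volumes
    into two-dimensional Mollweide-projected maps and recognises the
    stroke-affected brain-artery territory from those maps. Provides
    histogram-based background/brain/stroke intensity segmentation, radial
    spherical projection with max-value rasterisation, healthy diffusion-level
    reference maps with sigma-level flagging, a five-territory atlas
    (ACA, superior/inferior MCA, PCA, PICA), a two-criterion territory
    classifier with Youden-index cut-off optimisation, leave-p-out
    cross-validated diagnostic-accuracy statistics, and a synthetic brain
    phantom generator for end-to-end evaluation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
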