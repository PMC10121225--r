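Package: synaptoscreen
Title: Automated High-Content Synaptic Phenotyping and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for automated quantification of
    presynaptic density in high-content fluorescence screens of human
    neuron / astrocyte co-cultures. Converts three-channel (nuclear,
    dendrite, presynaptic) z-stack field images into per-field
    measurements via maximum projection, mutual-information channel
    alignment, plate-wide illumination correction, tubeness-based
    neurite segmentation, speckle-enhanced puncta detection and
    colocalization; performs plating-consistency quality control,
    plate-level normalization (percent-of-control and intra-plate
    Z-scores) and hit calling; and provides effect-size and
    normal-approximation power utilities for study design. A synthetic
    field and plate simulator with planted ground truth supports
    validation of every stage without real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Software
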