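Package: myconet
Title: Quantification of Mycorrhizal Hyphal Network Architecture from Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An image-analysis and assay pipeline for extraradical fungal
    (mycorrhizal) networks. Converts grayscale micrographs into cleaned binary
    masks and one-pixel skeletons, estimates the mass fractal dimension by box
    counting, measures surface density, and assembles spatial gradient profiles
    across regions of interest. Also fits qPCR copy-number to dry-biomass
    linear calibrations and computes quantum-dot phosphorus transfer efficiency
    per unit of fungal biomass. Includes a synthetic hyphal-network generator
    with known ground truth and exact analytic fractal fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png,
    tiff,
    optparse,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
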