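Package: retvasc
Title: Retinal Vascular Morphometry and Cardiovascular Risk Flagging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parameter-based analysis of the retinal vasculature from fundus
    photographs and artery/vein segmentation masks. Implements a fundus
    enhancement chain (border masking, green-channel CLAHE, gamma lookup),
    optic-disc zone geometry (zones A/B/C in optic-disc-diameter units),
    vessel skeletonization and graph extraction with cross-sectional width
    profiling, eleven vascular morphometry parameters (branching coefficient,
    junction exponent, mean vessel width, optimality ratio, tree path
    statistics, simple tortuosity, vessel diameter reduction, CRAE and CRVE
    by the Knudtson-Parr-Hubbard pairing, arteriovenous ratio, box-counting
    fractal dimension), reference-range risk flagging with an AND combination
    against an external classifier verdict, confusion-matrix performance
    metrics, and a synthetic fundus phantom generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
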