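Package: vascflow
Title: Kymograph Velocimetry, Murray's-Law Branching and Morphometrics for
    Transparent Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image-analysis chain for live imaging of transparent
    vascular beds: kymograph generation and rolling-average normalization along
    vessel center-line ROIs, signed blood-flow velocimetry by shift-maximizing
    autocorrelation with contrast gating, vessel-diameter measurement by
    full-width at half-minimum, volumetric-flow computation and Murray's-law
    branching-exponent fitting, cell-shape morphometrics (area, circularity
    with a sub-pixel perimeter estimator), corrected total fluorescence, and
    vascular-regression scoring from colony outlines. A synthetic-data module
    simulates particle-carrying vessel movies, flow-conserving bifurcating
    networks, labeled cell mosaics and before/after bed outlines with known
    ground truth, so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
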