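Package: smokesense
Title: Thermal Imaging and NIR Spectroscopy Tools to Detect Smoke
    Contamination in Grapevine Canopies and Berries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive detection of bushfire smoke contamination in
    vineyards. Extracts canopy temperature, the infrared index (Ig) and
    the crop water stress index (CWSI) from radiometric thermal images
    using painted-reference-leaf thresholds and grid subdivision, and
    classifies smoked versus control canopies with a one-hidden-layer
    feedforward network trained by a loop over classical algorithms with
    neuron trimming. Preprocesses berry near-infrared reflectance spectra
    (absorbance transform, 700-1100 nm window, Savitzky-Golay second
    derivative) and regresses smoke-taint marker compounds (guaiacol and
    its glycoconjugates in berries and wine) with the same network
    family. Includes a synthetic-scene and synthetic-spectra generator
    reproducing the statistical structure the analysis assumes, and
    evaluation utilities (ROC, through-origin regression, prediction-band
    outlier rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    tiff,
    pROC,
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
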