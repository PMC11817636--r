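Package: speclesion
Title: Multispectral Skin-Lesion Classification with Spectral-Cube CNNs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multispectral reflectance
    imaging of skin lesions. Generates calibrated 8-band reflectance cubes for
    three lesion classes (nevus, melanoma, basal cell carcinoma) from a
    chromophore-absorption phantom, performs flat-field/dark-frame reflectance
    calibration, and trains small convolutional networks (a six-layer 2D CNN
    and a 3D-convolution VGG-16 variant) under a stratified cross-validation
    protocol to quantify the classification advantage of full spectral cubes
    over an RGB-like three-band subset. Includes class-imbalance handling,
    geometric augmentation, confusion-matrix metrics, and input-gradient
    saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
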