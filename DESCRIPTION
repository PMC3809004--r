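Package: glycosims
Title: ToF-SIMS and SPR Imaging Analysis of Printed Glycan Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing printed carbohydrate (glycan) microarray
    surfaces by time-of-flight secondary ion mass spectrometry (ToF-SIMS)
    imaging and surface plasmon resonance imaging (SPRi). Provides a
    hyperspectral ion-count cube data model with continuous-mode imzML
    input/output, monoisotopic fragment mass calculation for peak assignment,
    background-thresholded peak picking, region-of-interest (ROI) spectrum
    extraction with total-ion normalization, principal component analysis of
    ROI spectra with loading-threshold ion selection, category ion-map
    reconstruction with Otsu binarization and RGB chemical maps, sensorgram
    extraction and concentric-ROI sweeps from SPRi reflectance stacks, 1:1
    Langmuir kinetic fitting, and SIMS-to-SPRi spatial agreement statistics.
    Includes simulators that generate co-registered synthetic SIMS cubes and
    SPRi stacks from a shared ground truth (printed spot with coffee-stain
    ring and wash-tail artifacts, Poisson counting noise, Langmuir binding)
    so that every analysis stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    tiff,
    png,
    minpack.lm,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
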