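Package: leafsai
Title: Adaptive Spectral Absorption Indices for Leaf Water Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates leaf equivalent water thickness (EWT, g/cm^2) and fuel
    moisture content (FMC) from hyperspectral leaf reflectance. Implements
    three spectral absorption indices (SAI_970, SAI_1200, SAI_1660) that
    locate each leaf's own absorption peak and shoulder wavelengths inside
    fixed search windows, so the index adapts to per-leaf spectral
    heterogeneity, together with ten classical fixed-band water indices
    (WI, SRWI, NDWI, RDI, RATIO_975, RATIO_1200, DWI, MSI, NDII, GVMI).
    Provides reflectance CSV readers (wide and long layouts), resampling to
    a 1-nm grid, replicate averaging, a leaf-like synthetic spectrum
    generator with known ground truth, and k-fold cross-validated
    index-to-water-status regression (linear, quadratic, exponential) with
    cross-validated R-squared and relative RMSE reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
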