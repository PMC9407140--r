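Package: teaspec
Title: Hyperspectral Chemometrics for Monitoring Black-Tea Withering and
    Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting tea polyphenols, free amino acids and
    caffeine content in tea leaves from visible/near-infrared hyperspectral
    images collected during black-tea withering and fermentation.  Covers the
    full calibration workflow: black/white reflectance correction of raw
    digital-number cubes and region-of-interest mean-spectrum extraction;
    reference-chemistry assay calculations with standard curves;
    multiplicative scatter correction, Savitzky-Golay smoothing and
    first-derivative preprocessing; characteristic-band selection by the
    successive projections algorithm (SPA), competitive adaptive reweighted
    sampling (CARS) and uninformative variable elimination (UVE); partial
    least squares, support vector and random forest regression with
    RPD-based evaluation; and plateau-based judgment of withering and
    fermentation degree.  Includes a synthetic-data generator (Beer-Lambert
    mixing of Gaussian pure-component spectra with scatter, drift and noise)
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
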