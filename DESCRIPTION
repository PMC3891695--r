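Package: pasturediff
Title: Single-Day Image Differencing to Count Large Animals in Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automated enumeration of large animals (cattle, horses, wild
    ungulates) from pairs of 3-band aerial images acquired on a single day.
    Implements per-image principal component analysis, absolute differencing of
    the first components, heuristic spectral thresholding, unsmoothed
    polygonization of connected change pixels with an area (spatial) filter,
    tie-point affine image-to-image registration with RMSE and mis-registration
    reporting, and the omission/commission accuracy framework with the
    detection-probability count correction. Includes a synthetic pasture-scene
    generator with known animal locations so the full pipeline is testable
    without flight imagery, and a minimal GeoTIFF reader/writer for 3-band
    reflectance rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
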