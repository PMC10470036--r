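Package: uavpheno
Title: Plot-Level Crop Trait Extraction from UAV Surface and Reflectance
    Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Extracts per-plot canopy traits of row crops (developed for
    potato breeding trials) from georeferenced digital surface models and
    multispectral reflectance rasters produced by UAV photogrammetry:
    per-plot base-plane estimation by sorted-percentile selection on a
    bare-soil survey, pixelwise canopy height and summed canopy volume,
    ground coverage, and red/red-edge vegetation indices (NDVI, NDRE,
    CIre, LCI) aggregated over plot polygons. Includes an analytic
    synthetic-field generator with closed-form ground truth and tools for
    comparing acquisitions at different ground sampling distances, plus a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
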