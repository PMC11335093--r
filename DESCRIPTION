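Package: uavpheno
Title: Plot-Level Phenotype Extraction from Multitemporal UAV Orthomosaics
Version: 0.1.0
Authors@R:
    person("Field Phenomics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts plot-level phenotypic traits from georeferenced UAV
    orthomosaics (RGB, multispectral, digital surface models) and polygon
    region-of-interest shapefiles: empirical-line radiometric calibration
    from reference panels, a formula engine with 21 preset vegetation
    indices plus user-defined expressions, zonal statistics with
    pixel-center masking, DSM-deviation plant height, empirical biomass
    formulas, and external-script image features. Batch extraction over
    flight dates writes date-foldered tables, shapefiles and an SQLite
    store, and a statistics suite provides multi-family growth-curve
    fitting with best-model selection, correlation screening, trait
    dynamic curves and per-date distribution summaries. Includes a seeded
    synthetic field generator with known ground truth for end-to-end
    validation, plus self-contained GeoTIFF and ESRI shapefile readers and
    writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
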