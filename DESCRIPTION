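Package: dasypop
Title: Dasymetric Gridded Population Projections from Coupled SSP-RCP Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Distributes country-level Shared Socio-economic Pathway (SSP)
    urban and rural population scenarios onto a fine longitude-latitude grid
    so that the spatial pattern of urban pixels conforms to Representative
    Concentration Pathway (RCP) urban-fraction grids, iterated annually.
    Provides a tie-free "unique population" ranking surface built from
    rescaled inverse distances to roads and to per-cell population centres of
    gravity, top-k urban-mask selection within each coarse cell,
    mass-conserving proportional allotment within country by urban/rural
    strata, zonal validation (r-squared and RMSE against reference totals),
    a self-contained synthetic-world generator for testing, and GeoTIFF,
    GeoJSON and CSV input/output matching the published dataset conventions
    (32-bit float samples, nodata -9999, WGS84 geographic referencing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
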