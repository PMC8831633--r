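Package: climstab
Title: Climate Stability Index Mapping from Multi-Temporal Bioclimatic Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes Climate Stability Index (CSI) maps from gridded
    bioclimatic variables spanning multiple time periods. Provides per-pixel
    temporal dispersion statistics (sample standard deviation and range) over
    raster time stacks, median/mean reduction of general circulation model
    (GCM) ensembles for future scenarios, land/sea masking rules for
    sea-level change across glacial cycles, Pearson-correlation based
    collinearity pruning of candidate variables, min-max normalization and
    index composition, a robustness-validation harness comparing statistic,
    reducer and threshold choices, and a seeded synthetic-world generator so
    the whole pipeline is testable without external climate downloads.
    Includes a minimal single-band GeoTIFF reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    matrixStats,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
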