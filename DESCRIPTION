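Package: heatnpp
Title: Decomposing Ocean Net Primary Production Anomalies Under Marine
    Heatwaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how marine heatwaves (MHWs) restructure the
    drivers of ocean net primary production (NPP) on monthly gridded fields.
    Builds fixed-baseline monthly climatologies and labels every cell-month
    as MHW, moderate warm (positive SST anomaly below the MHW threshold), or
    other; partitions NPP anomalies per cell into SST-dependent and
    SST-independent components with a two-stage least-squares decomposition;
    classifies cells by dominant driver and by the sign and significance of
    the SSTA-NPPA correlation; and aggregates results into area-weighted
    regional, latitude-band, and box-plot-style summaries. Ships a seeded
    synthetic-scene generator with known ground-truth coefficients
    (including an Eppley-VGPM forward model for NPP) so every stage of the
    pipeline is testable without external satellite or reanalysis downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ncdf4,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
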