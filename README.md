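# heatnpp

Quantifying how marine heatwaves restructure the drivers of ocean net
primary production, on monthly gridded fields.

Marine heatwaves (MHWs) — months in which sea surface temperature (SST)
exceeds the seasonally varying 90th percentile of a fixed baseline
climatology — perturb phytoplankton productivity through temperature itself
and through the chlorophyll (CHL) and light (PAR) changes that travel with
warm anomalies. `heatnpp` is for biological oceanographers and marine
ecosystem analysts who want to separate those channels on gridded monthly
data: it labels every cell-month as MHW, moderate warm (positive SST anomaly
below the MHW threshold, "SSTA⁺"), or other; decomposes the NPP anomaly per
cell into SST-dependent and SST-independent components; classifies cells by
dominant driver and by the sign and significance of the NPPA–SSTA
correlation (MHW-enhanced vs MHW-inhibited); and aggregates the results
with cos-latitude area weights into regional, latitude-band, and
box-plot-style summaries.

## The model

Stage 1 regresses the CHL and PAR anomalies on the SST anomaly
(per cell, ordinary least squares, no intercept):

    CHLA = α·SSTA + CHLA_res        PARA = β·SSTA + PARA_res

Stage 2 partitions the NPP anomaly into six terms:

    NPPA = a·SSTA + b·CHLA_sst + c·PARA_sst     (SST-dependent)
         + d·CHLA_res + e·PARA_res + NPPA_res   (SST-independent)

where `CHLA_sst = α·SSTA`, `PARA_sst = β·SSTA`. The six-term budget sums to
NPPA exactly at every cell-month. Because the three SST-linked regressors
are proportional to SSTA, the fit runs on the identifiable design
`(SSTA, CHLA_res, PARA_res)` and allocates the total SSTA slope with the
convention `b = d`, `c = e` (a multiplicative NPP model responds to a CHL or
PAR fluctuation identically whether SST drove it); see the methods vignette
(`vignettes/decomposing-npp-under-mhws.Rmd`) for the full rationale.

Real multi-decade satellite/reanalysis inputs are out of scope; the package
ships a seeded synthetic-scene generator with known ground truth (including
an Eppley-VGPM forward model, in which the optimal photosynthetic rate grows
exponentially with SST) so every stage is testable offline, plus CF-style
NetCDF readers/writers for gridded monthly series.

## Worked example

```r
library(heatnpp)

cfg    <- scene_config(n_lat = 10, n_lon = 20, seed = 1)  # 200 cells x 252 months
scene  <- simulate_scene(cfg)
clim   <- monthly_climatology(scene$sst, q = 0.90)
labels <- label_conditions(scene$sst, clim)
print(labels)
#> <condition_labels>
#>     OTHER SSTA_PLUS       MHW      <NA>
#>     25181     20419      4800         0
```

About 9.5% of cell-months are MHWs — by construction close to `1 - q`.
Decompose the NPP anomaly and check recovery of the generating
coefficients:

```r
ssta   <- anomalies(scene$sst, clim)
anom   <- function(x) anomalies(x, monthly_climatology(x))
decomp <- decompose_grid(ssta, anom(scene$chl), anom(scene$par), anom(scene$npp))
round(c(alpha_hat = mean(decomp$maps$alpha), alpha_true = scene$truth$alpha,
        d_hat = mean(decomp$maps$d), d_true = scene$truth$d), 4)
#>  alpha_hat alpha_true      d_hat     d_true
#>    -0.0501    -0.0500   447.6184   450.0000
```

Composite the budget over MHW months, map the dominant driver, and classify
the NPPA–SSTA response at the 90% confidence level:

```r
cmp <- composite_components(decomp, labels, "MHW")
dom <- dominance_map(cmp)
round(100 * area_fraction(dom, "SST_DEPENDENT"), 1)
#> [1] 54.7     # % of (cos-latitude-weighted) area SST-dependent during MHWs

classes <- response_class_map(anom(scene$npp), ssta, alpha_sig = 0.10)
round(100 * c(enhanced  = area_fraction(classes, "ENHANCED"),
              inhibited = area_fraction(classes, "INHIBITED")), 1)
#>  enhanced inhibited
#>       1.3      28.5
```

The default scene couples NPP negatively to SSTA overall
(`a + b·α + c·β = -4.3` mg C m⁻² day⁻¹ per °C), so a substantial fraction of
cells is MHW-inhibited and almost none MHW-enhanced — a "suppression" regime.
`regime_shift_config()` generates a scene whose SST-coupled pathway is
amplified during extreme-warm months, demonstrating the dominance shift from
SST-independent toward SST-dependent control between SSTA⁺ and MHW
conditions.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → label → decompose → classify → summarize), writing
NetCDF and CSV outputs under `results/`. `run_pipeline(pipeline_config(...))`
does it in one call with a reproducibility manifest.

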