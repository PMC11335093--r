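# uavpheno

Plot-level phenotypic trait extraction from multitemporal UAV imagery,
for field-trial researchers who have orthomosaics and plot polygons and
need a per-plot, per-date trait table — without assembling a GIS stack.

Given georeferenced rasters (RGB and multispectral orthomosaics, digital
surface models) and plot regions of interest (ROIs) in a shapefile, the
package:

* converts multispectral digital numbers to reflectance by the
  **empirical line method** — per band, ordinary least squares through
  calibration panels of known reflectance, `rho = gain * DN + offset`;
* evaluates **vegetation-index formulas** over canonical band variables
  (`r, g, b, re, nir`), with 21 standard presets (NDVI, ExG, ExR, OSAVI,
  NDRE, ...) plus user-defined expressions;
* computes **zonal statistics** per plot with a deterministic
  pixel-center-in-polygon mask, **plant height** as the mean DSM
  deviation from a soil reference, **biomass** from user-supplied
  empirical formulas, and features from **external scripts** (e.g. a
  deep-learning trait model) via a simple subprocess protocol;
* runs **multitemporal batches**, writing date-foldered CSV/XLSX tables,
  shapefiles with appended trait columns, plot clips, and an optional
  SQLite database, plus a throughput report (plots/min);
* provides an **analysis suite**: five-family growth-curve fitting with
  best-set selection by RMSE (ties at 4 decimals reported), Pearson
  correlation screening against ground truth, trait dynamic curves, and
  per-date box statistics with 1.5 IQR outliers;
* ships a **seeded synthetic field generator** with closed-form ground
  truth, so the entire chain is testable without any real imagery.

GeoTIFF and ESRI shapefile readers/writers are built in (uncompressed,
strip-based TIFF subset; polygon shapefiles) — no external GIS
dependencies.

## Worked example

Synthesise a small field with known truth, calibrate, and extract four
traits for every plot:

```r
library(uavpheno)
truth <- field_truth(n_rows = 2, n_cols = 3, noise_dn = 2, seed = 1)
paths <- generate_field(truth, gsd = 5, out_dir = file.path(tempdir(), "demo"))
stub  <- generate_stub_script(file.path(tempdir(), "stub.sh"), "constant", 2.5)

strategy <- extraction_strategy(list(
  feature_formula("NDVI", get_preset("NDVI", "MS"),  source = "ms"),
  feature_formula("EXG",  get_preset("EXG",  "RGB"), source = "rgb"),
  feature_height("height", ground = truth$ground_elev),
  feature_external("LRS", external_feature_spec(stub$interpreter, stub$script))))

task <- batch_task("demo",
  dates = list("2024-07-01" = list(
    ms = paths$ms, rgb = paths$rgb, dsm = paths$dsm,
    panels = list(shp = paths$panels_shp, csv = paths$panels_csv))),
  roi_path = paths$rois, strategy = strategy, id_field = "plot_id",
  output_root = file.path(tempdir(), "out"))

res <- run_batch(task)
head(phenotype_wide(res$table))
#>         date plot_id      NDVI         EXG    height LRS
#> 1 2024-07-01   P0001 0.7914883  0.71058047 0.7860555 2.5
#> 2 2024-07-01   P0002 0.7767953  0.64392908 0.8800556 2.5
#> 3 2024-07-01   P0003 0.6688370  0.38669506 0.7947420 2.5
#> 4 2024-07-01   P0004 0.6528658 -0.05826437 0.5490838 2.5
#> 5 2024-07-01   P0005 0.8556694  0.26421483 1.0619389 2.5
#> 6 2024-07-01   P0006 0.6483909 -0.08466232 0.9350111 2.5
```

Each row is one plot on one date. The extracted values sit within the
per-pixel noise of the generator's truth (plot P0001: true NDVI
0.7912051, EXG 0.7072800, height 0.7856641 m); with `noise_dn = 0` they
agree to 1e-9, which is what the acceptance suite asserts at 234 plots x
4 dates. `LRS` is the external-script feature (here a stub printing
2.5, standing in for a leaf-rolling-score model). On disk,
`out/20240701/demo_<timestamp>/` now holds the CSV, the shapefile with
trait columns, the calibration report and the plot clips.

Fitting a growth relation to screened traits:

```r
fit_curves(truth$plots$height, y,          # y: measured fresh weight
           families = c("linear", "exponential", "logarithmic"))
#> <fit_curves>
#>   linear       rmse 0.00800229  R2 0.9923  coef (0.172677, 0.576767)  <- best
#>   exponential  rmse 0.00954231  R2 0.9891  coef (0.304847, 0.902889)
#>   logarithmic  rmse 0.0143071   R2 0.9755  coef (0.742233, 0.439541)
```

A command-line interface covers the same flow
(`inst/cli/uavpheno synth|roi|batch|analyze`, see `?uavpheno_cli`).

## Scope

Orthomosaic generation, DSM production and automatic plot segmentation
are upstream concerns and out of scope; ROIs are drawn manually or
replicated from a template (`replicate_roi`). See the vignette
(`vignettes/uav-plot-phenotyping.Rmd`) for the model conventions, the
numerical choices and what the synthetic world does and does not
establish.
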