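---
title: "Plot-level phenotype extraction from UAV orthomosaics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-level phenotype extraction from UAV orthomosaics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Field phenotyping trials fly a UAV repeatedly over a grid of small plots
(one variety x replication each) carrying RGB, multispectral (MS) and —
via photogrammetry — surface-elevation (DSM) sensors. The products are
georeferenced orthomosaics; the quantity of scientific interest is a table
of *plot-level* traits per flight date: vegetation indices (VIs), canopy
height, derived biomass, and features predicted by external models. This
package implements that extraction chain end to end: polygon regions of
interest (ROIs) over a raster, empirical-line radiometric calibration, a
formula engine for VIs, zonal statistics, batch orchestration over dates,
persistence (CSV/XLSX, shapefile, SQLite), and a statistics suite for
screening and growth-curve fitting.

```{r, eval = FALSE}
library(uavpheno)
truth <- field_truth(n_rows = 2, n_cols = 3, noise_dn = 0, seed = 7)
paths <- generate_field(truth, gsd = 5, out_dir = tempdir())
```

## Geodata conventions

**Containers.** A `raster_grid` is an `[rows, cols, bands]` double array
with a GDAL-style geotransform (top-left origin, north-up, axis-aligned)
and `NA` for nodata; a `plot_roi` is a labeled polygon (outer ring plus
optional holes) in world coordinates. The environment this package
targets has no GIS stack, so GeoTIFF and ESRI shapefile I/O are
implemented internally for the uncompressed, strip-based subset that UAV
processing chains commonly emit; round-trips are exact for integer grids
and to IEEE-double precision for float grids, and the writers have been
cross-validated against independent readers (`tifffile`, `shapely`) in
the test suite.

**Pixel-inclusion rule.** Clipping masks a pixel *in* iff its CENTER lies
inside the polygon, with the boundary counting as inside (closed-boundary
convention). This is deterministic and oracle-testable: the test suite
checks every mask against an exhaustive per-pixel point-in-polygon
routine and against `shapely`. No resampling or reprojection ever
happens; a CRS mismatch between raster and ROI is an error, because
silent reprojection would hide the inter-date registration errors that
plague multitemporal stacks. Sensors with different ground sampling
distances (GSD) are therefore clipped each at their own native grid.

**Nodata.** A nodata value in any referenced band makes that pixel
missing for every downstream formula, and zonal statistics are computed
over contributing pixels only (the count is always reported; fewer than
5 contributors logs a warning but still reports the value).

## Radiometric calibration

Digital numbers (DN) are converted to reflectance by the empirical line
method: for each band, ordinary least squares of the panels' known
reflectance on the panel-mean DN,

$$\rho = \text{gain} \cdot DN + \text{offset}.$$

Choices that the method description leaves open, fixed here:

* **Regression direction** — reflectance regressed on DN (the
  operational direction of use).
* **Panel statistic** — mean of pixel-center-contained pixels, no
  outlier trimming.
* **Intercept** — fitted, not forced through zero (the standard
  two-parameter empirical line).
* **Range handling** — calibrated values below 0 or above 1 are retained
  by default (with a warned count) so that linearity is preserved for
  normalized indices; `clamp = TRUE` clips to [0, 1].
* **Scope** — one model per image; per-date pooling is not attempted.

With the three standard panels (reflectance 0.12, 0.32, 0.56) the fit is
exact when panel DNs are collinear, and the per-band $R^2$ reported in
`calibration.csv` mirrors the per-image accuracy reporting of field
practice. The synthetic generator inverts this model
($DN = (\rho - \text{offset})/\text{gain}$ + noise) precisely so the
whole DN-to-index chain is exercised by recovery tests.

## The formula engine

Trait formulas are text expressions over the canonical band variables
`r, g, b, re, nir` (plus `dsm` and previously computed trait names),
with `+ - * / ^` at conventional precedence, `**` as a power alias,
parentheses, unary minus and `sqrt`. Evaluation is element-wise;
division by zero, negative square-root arguments and missing inputs all
produce missing values rather than errors, because a handful of
degenerate pixels must not poison a plot statistic.

The registry ships the 21 standard presets (10 visible-band indices
usable by RGB or MS sensors; 11 requiring red-edge/NIR, MS only).
Two fidelity notes:

* **MSAVI** is registered *as published in the source table*, i.e.
  without the conventional final division by two; the conventional form
  is available as `MSAVI_std`. Tests pin both.
* **CIVE**'s additive constant (18.78745) is applied to whatever scale
  the image carries (reflectance or DN); the choice of input image is
  the user's and is recorded in the strategy.

Indices can be evaluated per pixel and then aggregated (default), or the
band means can be aggregated first and the formula applied to them
(`eval_mode = "band_mean"`). The two differ for nonlinear formulas; the
default follows the interpretation that clipping precedes "statistical
and numerical calculations", and both paths are tested.

## Extraction and batching

An `extraction_strategy` is an ordered list of feature specs: formula
(source image role + zonal statistic), height, biomass, external.
Plant height is the mean DSM deviation over the plot — `mean(DSM) -
ground` for a scalar soil elevation, or the mean per-pixel `DSM - DTM`
difference when a bare-soil raster is available; a missing soil
reference is an error, not a silent zero. Biomass evaluates an empirical
formula (typically exported from the curve-fitting module) over traits
computed earlier in the order; the strategy constructor enforces that
ordering statically.

External features follow a subprocess protocol chosen here as the
concrete form of "local commands to a Python interpreter": the clip is
written as `<plot_id>.tif` into the run folder (and retained), the
script is invoked as `interpreter script image_path plot_id
[extra_args]`, and the LAST stdout line must be one numeric literal.
Nonzero exit, timeout (default 60 s) or non-numeric output yield a
missing value and a log entry; a missing interpreter or script aborts
before the batch starts. One value per invocation per plot.

`run_batch` loops dates, calibrates MS imagery when panels are supplied,
extracts every plot, and writes per-date outputs under
`output_root/YYYYMMDD/<task>_<UTC timestamp>/` (a new timestamped folder
per run, never overwriting): wide CSV, ROI shapefile with appended trait
columns (DBF names truncated to 10 characters with a warned mapping),
clips, calibration report, plus an optional SQLite long table with a
uniqueness constraint on `(date, plot_id, trait)`. Failures are missing
cells, never dropped rows, so the long table always has
`dates x plots x traits` rows. Timing covers the extraction loop only,
and `compute_efficiency` reports plots x periods / mean-minutes, the
mean taken at full precision with 2-decimal values alongside — the
rounding convention that reproduces all 16 published benchmark rows.

## Statistics suite

`fit_curves` fits five families on the original scale — linear,
quadratic, exponential ($a e^{bx}$), power ($a x^b$), logarithmic
($a + b\ln x$) — the published account names five defaults but
enumerates only linear, quadratic and exponential in its results; power
and logarithmic complete the set here and are substitutable. Nonlinear
families are initialised by log-linearisation and refined by BFGS on the
residual sum of squares, which survives the zero-residual case where
Gauss-Newton solvers fail. The best set is *every* family tied for
minimal RMSE at 4-decimal rounding, matching the published tie of two
families at RMSE 0.1201; ties are reported, not broken. Because the
quadratic family nests the linear one (under noise its RMSE is almost
always strictly smaller at that rounding), generator-recovery checks are
run among well-separated families (linear vs exponential vs
logarithmic) via the `families` argument.

Correlation screening uses Pearson coefficients (pairwise-complete),
with variables ranked by absolute correlation against a designated truth
column. Distribution statistics use linear-interpolation quartiles
(R type 7) and the 1.5 IQR outlier rule. `accuracy_report` returns
$R^2$, RMSE and rRMSE = 100 RMSE / mean(observed); the denominator
choice (mean rather than range or max) is an assumption, flagged here.

## The synthetic world

`field_truth`/`generate_field` emulate a rice trial at case-study scale:
a 13 x 18 grid (234 plots — 78 accessions x 3 replications) of 1.5 m
plots with 0.5 m alleys, per-plot reflectances drawn once per seed from
plausible canopy ranges (visible low, red edge intermediate, NIR high),
heights 0.4-1.2 m on a flat soil plane, three flat-spectrum panels at
0.12/0.32/0.56, calibration truth gain 0.001 / offset 0.02, and Gaussian
per-pixel noise (default 2 DN; 1 cm DSM). Plot edges are aligned to
pixel boundaries so each plot is a uniform block and closed-form truth
values (NDVI, EXG, height) are exact targets. What the generator does
*not* simulate — canopy texture, shadows, soil mixing at plot borders,
geometric misregistration between dates — bounds what a green test
establishes: correctness of the extraction arithmetic and plumbing, not
robustness to real-scene effects.

## Known limitations

* Orthomosaic generation, DSM production and automatic plot segmentation
  are out of scope (they are performed upstream by photogrammetry
  tools; ROIs are drawn manually or replicated from a template).
* The published field results (model accuracy R² 0.70 / RMSE 0.87 /
  rRMSE 22.86 %; the height-biomass fits) depend on unavailable imagery
  and model weights and are not reproduced; parameter-recovery tests on
  the synthetic world stand in for them.
* The GeoTIFF codec reads uncompressed strip- or planar-organised
  classic TIFFs only; compressed or tiled inputs must be converted
  upstream.
* No vegetation/soil masking is applied before zonal statistics.
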