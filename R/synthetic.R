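# Seeded synthetic-field generator: orthomosaics, DSM, ROIs, calibration
# panels and a ground-truth table with known per-plot values, so the whole
# extraction chain is testable without any real imagery.

#' Synthetic field ground truth
#'
#' Describes a rectangular grid of rectangular plots with known per-plot
#' band reflectances and canopy heights, plus the calibration model and
#' noise levels used to synthesise digital numbers. Defaults emulate a
#' rice field trial at UAV scale: 1.5 m plots with 0.5 m alleys, canopy
#' reflectance drawn per plot from agronomically plausible ranges
#' (visible bands low, red edge intermediate, near infrared high), heights
#' 0.4-1.2 m over a flat soil plane, and an empirical-line model with gain
#' 0.001 and offset 0.02 (reflectance per DN).
#'
#' @param n_rows,n_cols plot grid dimensions (`n_rows * n_cols` plots).
#' @param plot_w,plot_h plot size in metres.
#' @param alley alley width between plots in metres.
#' @param origin world coordinates (x, y) of the field's top-left corner.
#' @param crs CRS identifier.
#' @param ground_elev soil-plane elevation in metres.
#' @param gain,offset calibration truth (reflectance = gain * DN + offset).
#' @param panel_reflectance reflectances of the calibration panels placed
#'   in the alley below the field. Default `c(0.12, 0.32, 0.56)`.
#' @param noise_dn per-pixel Gaussian sigma of the synthesised DN.
#' @param noise_dsm per-pixel Gaussian sigma of the DSM in metres.
#' @param seed RNG seed: identical seeds give bit-identical outputs.
#' @return object of class `field_truth` with a `plots` data.frame holding
#'   per-plot reflectances, height, and closed-form NDVI/EXG.
#' @export
field_truth <- function(n_rows = 13, n_cols = 18, plot_w = 1.5,
                        plot_h = 1.5, alley = 0.5,
                        origin = c(500000, 3370000), crs = "EPSG:32649",
                        ground_elev = 20, gain = 0.001, offset = 0.02,
                        panel_reflectance = c(0.12, 0.32, 0.56),
                        noise_dn = 2, noise_dsm = 0.01, seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, plot_w > 0, plot_h > 0, alley >= 0,
            noise_dn >= 0, noise_dsm >= 0, gain != 0)
  n <- n_rows * n_cols
  set.seed(seed)
  plots <- data.frame(
    plot_id = sprintf("P%04d", seq_len(n)),
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows),
    r = runif(n, 0.03, 0.10),
    g = runif(n, 0.06, 0.15),
    b = runif(n, 0.02, 0.08),
    re = runif(n, 0.15, 0.30),
    nir = runif(n, 0.35, 0.60),
    height = runif(n, 0.4, 1.2),
    stringsAsFactors = FALSE)
  plots$NDVI <- (plots$nir - plots$r) / (plots$nir + plots$r)
  plots$EXG <- (plots$g * 2 - plots$r - plots$b) /
    (plots$r + plots$g + plots$b)
  structure(list(n_rows = n_rows, n_cols = n_cols, plot_w = plot_w,
                 plot_h = plot_h, alley = alley, origin = origin,
                 crs = crs, ground_elev = ground_elev, gain = gain,
                 offset = offset, panel_reflectance = panel_reflectance,
                 noise_dn = noise_dn, noise_dsm = noise_dsm, seed = seed,
                 plots = plots),
            class = "field_truth")
}

.field_plot_rois <- function(truth) {
  pitch_x <- truth$plot_w + truth$alley
  pitch_y <- truth$plot_h + truth$alley
  ox <- truth$origin[1] + truth$alley
  oy <- truth$origin[2] - truth$alley
  lapply(seq_len(nrow(truth$plots)), function(i) {
    r <- truth$plots$row[i]; c_ <- truth$plots$col[i]
    x0 <- ox + (c_ - 1) * pitch_x
    y0 <- oy - (r - 1) * pitch_y
    plot_roi(truth$plots$plot_id[i],
             rbind(c(x0, y0), c(x0 + truth$plot_w, y0),
                   c(x0 + truth$plot_w, y0 - truth$plot_h),
                   c(x0, y0 - truth$plot_h)),
             attributes = list(row = r, col = c_), crs = truth$crs)
  })
}

.field_panel_polys <- function(truth, panel_size = 0.5) {
  # panels sit in the clear strip below the plot grid
  y0 <- truth$origin[2] - truth$alley -
    truth$n_rows * (truth$plot_h + truth$alley) - 0.5
  lapply(seq_along(truth$panel_reflectance), function(k) {
    x0 <- truth$origin[1] + truth$alley + (k - 1) * (panel_size + 0.5)
    rbind(c(x0, y0), c(x0 + panel_size, y0),
          c(x0 + panel_size, y0 - panel_size), c(x0, y0 - panel_size))
  })
}

#' Generate a synthetic field data set on disk
#'
#' Writes, under `out_dir`: `ms.tif` (5-band digital numbers synthesised
#' by inverting the calibration model: `DN = (rho - offset)/gain` + noise,
#' so the full DN -> reflectance -> index chain is exercised), `rgb.tif`
#' (visible reflectance scaled to 0-255 + noise), `dsm.tif` (soil plane +
#' plot height + noise), `rois.shp`, `panels.shp` + `panels.csv`, and
#' `truth.csv` with all per-plot values including closed-form NDVI and
#' EXG. Pixels are aligned so plot edges fall on pixel boundaries and
#' every inside pixel carries the plot's uniform value.
#'
#' @param truth a [field_truth()].
#' @param gsd ground sampling distance in cm/pixel; must give each plot
#'   at least 25 pixels.
#' @param out_dir output directory (created if needed).
#' @return named list of the written paths.
#' @export
generate_field <- function(truth, gsd = 5, out_dir) {
  px <- gsd / 100  # metres per pixel
  if ((truth$plot_w / px) * (truth$plot_h / px) < 25)
    stop("gsd too coarse: plots must contain at least 25 pixels")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(truth$seed + 1L)

  pitch_x <- truth$plot_w + truth$alley
  pitch_y <- truth$plot_h + truth$alley
  width_m <- truth$alley + truth$n_cols * pitch_x
  panel_strip <- 2.0
  height_m <- truth$alley + truth$n_rows * pitch_y + panel_strip
  w <- ceiling(width_m / px)
  h <- ceiling(height_m / px)
  gt <- c(truth$origin[1], px, 0, truth$origin[2], 0, -px)

  rois <- .field_plot_rois(truth)
  panel_polys <- .field_panel_polys(truth)

  # soil background reflectance (flat spectrum), then paint plots
  soil <- c(r = 0.20, g = 0.18, b = 0.15, re = 0.25, nir = 0.30)
  refl <- array(NA_real_, dim = c(h, w, 5))
  band_names <- c("b", "g", "r", "re", "nir")  # MS band order on disk
  for (bi in seq_along(band_names))
    refl[, , bi] <- soil[[band_names[bi]]]
  dsm <- matrix(truth$ground_elev, nrow = h, ncol = w)

  ctr_x <- gt[1] + (seq_len(w) - 0.5) * px
  ctr_y <- gt[4] - (seq_len(h) - 0.5) * px
  paint <- function(poly, setter) {
    ring <- if (is.matrix(poly)) poly else poly$outer
    cols <- which(ctr_x > min(ring[, 1]) & ctr_x < max(ring[, 1]))
    rows <- which(ctr_y < max(ring[, 2]) & ctr_y > min(ring[, 2]))
    if (length(rows) && length(cols)) setter(rows, cols)
  }
  for (i in seq_len(nrow(truth$plots))) {
    p <- truth$plots[i, ]
    paint(rois[[i]]$polygon$outer, function(rows, cols) {
      for (bi in seq_along(band_names))
        refl[rows, cols, bi] <<- p[[band_names[bi]]]
      dsm[rows, cols] <<- truth$ground_elev + p$height
    })
  }
  for (k in seq_along(panel_polys)) {
    rho <- truth$panel_reflectance[k]
    paint(panel_polys[[k]], function(rows, cols) {
      refl[rows, cols, ] <<- rho
    })
  }

  # MS digital numbers by inverting the calibration model
  dn <- (refl - truth$offset) / truth$gain
  if (truth$noise_dn > 0)
    dn <- dn + array(stats::rnorm(length(dn), 0, truth$noise_dn), dim(dn))
  ms_path <- file.path(out_dir, "ms.tif")
  write_raster(raster_grid(dn, gt, crs = truth$crs, datatype = "Float64"),
               ms_path)

  # RGB: visible reflectance scaled to an 8-bit-like range (kept float so
  # sigma = 0 recovery is exact); band order r, g, b
  rgb <- array(NA_real_, dim = c(h, w, 3))
  rgb[, , 1] <- refl[, , 3] * 255
  rgb[, , 2] <- refl[, , 2] * 255
  rgb[, , 3] <- refl[, , 1] * 255
  if (truth$noise_dn > 0)
    rgb <- rgb + array(stats::rnorm(length(rgb), 0, truth$noise_dn),
                       dim(rgb))
  rgb_path <- file.path(out_dir, "rgb.tif")
  write_raster(raster_grid(rgb, gt, crs = truth$crs, datatype = "Float64"),
               rgb_path)

  if (truth$noise_dsm > 0)
    dsm <- dsm + matrix(stats::rnorm(length(dsm), 0, truth$noise_dsm),
                        nrow = h)
  dsm_path <- file.path(out_dir, "dsm.tif")
  write_raster(raster_grid(dsm, gt, crs = truth$crs, datatype = "Float64"),
               dsm_path)

  roi_path <- file.path(out_dir, "rois.shp")
  write_rois(rois, roi_path)

  panel_rois <- lapply(seq_along(panel_polys), function(k)
    plot_roi(sprintf("panel%d", k), panel_polys[[k]],
             attributes = list(panel_id = sprintf("panel%d", k)),
             crs = truth$crs))
  panels_shp <- file.path(out_dir, "panels.shp")
  write_rois(panel_rois, panels_shp)
  panels_csv <- file.path(out_dir, "panels.csv")
  utils::write.csv(data.frame(panel_id = sprintf("panel%d",
                                                 seq_along(panel_polys)),
                              reflectance = truth$panel_reflectance),
                   panels_csv, row.names = FALSE)

  truth_csv <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth$plots, truth_csv, row.names = FALSE)

  list(ms = ms_path, rgb = rgb_path, dsm = dsm_path, rois = roi_path,
       panels_shp = panels_shp, panels_csv = panels_csv, truth = truth_csv)
}

#' Generate an external feature stub script
#'
#' Writes an executable script honoring the external-feature protocol
#' (`interpreter script image_path plot_id ...`; last stdout line is the
#' value). Three behaviors: `"constant"` prints `value`; `"fail"` exits
#' with status 1; `"mean"` prints the mean non-nodata pixel value of the
#' clip (a Python script using tifffile, standing in for a model such as a
#' leaf-rolling-score network).
#'
#' @param out_path script path to create.
#' @param behavior `"constant"`, `"fail"`, or `"mean"`.
#' @param value constant to print for `behavior = "constant"`.
#' @return list with `interpreter` and `script` ready for
#'   [external_feature_spec()].
#' @export
generate_stub_script <- function(out_path, behavior = c("constant", "fail",
                                                        "mean"),
                                 value = 2.5) {
  behavior <- match.arg(behavior)
  if (behavior == "mean") {
    writeLines(c(
      "import sys",
      "import numpy as np",
      "import tifffile",
      "a = tifffile.imread(sys.argv[1]).astype(float)",
      "nodata = -1.7e+308",
      "vals = a[a > nodata / 2]",
      "print('plot', sys.argv[2])",
      "print(float(np.mean(vals)))"), out_path)
    interpreter <- Sys.which("python")
  } else {
    body <- if (behavior == "constant")
      c("#!/bin/sh", paste0("echo ", format(value, digits = 15)))
    else c("#!/bin/sh", "echo broken >&2", "exit 1")
    writeLines(body, out_path)
    interpreter <- "/bin/sh"
  }
  Sys.chmod(out_path, "755")
  list(interpreter = unname(interpreter), script = out_path)
}
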