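# extraction: zonal statistics, height, biomass, external features,
# whole-plot extraction.

test_that("zonal statistics match brute-force enumeration", {
  clip <- raster_grid(matrix(c(1, 2, 3, 4, NA, NA), 2),
                      c(0, 1, 0, 2, 0, -1))
  expect_equal(zonal_stat(clip, "mean"), list(value = 2.5, n = 4L))
  expect_equal(zonal_stat(clip, "max")$value, 4)
  expect_equal(zonal_stat(clip, "min")$value, 1)
  expect_equal(zonal_stat(clip, "median")$value, 2.5)
  expect_equal(zonal_stat(clip, "std")$value, sd(1:4))
  expect_equal(zonal_stat(clip, "sum")$value, 10)
  expect_equal(zonal_stat(clip, "count")$value, 4)
  expect_error(zonal_stat(clip, "mode"), "unknown statistic")
  const <- raster_grid(matrix(5, 3, 3), c(0, 1, 0, 3, 0, -1))
  expect_equal(zonal_stat(const, "mean")$value, 5)
  empty <- raster_grid(matrix(NA_real_, 2, 2), c(0, 1, 0, 2, 0, -1))
  expect_warning(res <- zonal_stat(empty, "mean"), "no contributing")
  expect_true(is.na(res$value))
  expect_identical(res$n, 0L)
})

test_that("every statistic equals exhaustive recomputation on random clips", {
  set.seed(31)
  r <- tiny_raster(24, 24, origin = c(0, 24))
  r$values[, , 1] <- matrix(rnorm(24 * 24), 24)
  stats_fns <- list(mean = mean, median = median, min = min, max = max,
                    std = sd, sum = sum,
                    count = function(v) as.double(length(v)))
  for (k in 1:10) {
    roi <- plot_roi(paste0("Z", k),
                    random_polygon(runif(2, 5, 19), runif(1, 2, 6),
                                   sample(3:7, 1)), crs = "EPSG:32649")
    clip <- suppressWarnings(clip_plot(r, roi))
    mask <- oracle_mask(r, roi)
    vals <- r$values[, , 1][mask]
    for (nm in names(stats_fns)) {
      got <- suppressWarnings(zonal_stat(clip, nm))
      if (length(vals) == 0) {
        expect_true(is.na(got$value))
      } else {
        expect_equal(got$value, stats_fns[[nm]](vals), label = nm)
        expect_equal(got$n, length(vals))
      }
    }
  }
})

test_that("height is the mean DSM deviation from the ground reference", {
  dsm <- raster_grid(matrix(1.8, 6, 6), c(0, 1, 0, 6, 0, -1),
                     crs = "EPSG:32649")
  roi <- square_roi("H", 1, 5, 3)
  expect_equal(extract_height(dsm, roi, ground = 0.6)$value, 1.2)
  # DTM equal to DSM: zero height
  expect_equal(extract_height(dsm, roi, ground = dsm)$value, 0)
  # nodata holes: mean over remaining pixels, count reported
  dsm2 <- dsm
  dsm2$values[2, 2:3, 1] <- NA
  dsm2$values[3, 2, 1] <- 2.4
  res <- extract_height(dsm2, roi, ground = 0.6)
  vals <- c(rep(1.8, 6), 2.4)  # 9 pixels - 2 missing, one altered
  expect_equal(res$n, 7L)
  expect_equal(res$value, mean(vals) - 0.6)
  expect_error(extract_height(dsm, roi), "no soil reference")
  # mismatched DTM grid
  dtm_small <- raster_grid(matrix(0, 3, 3), c(0, 1, 0, 3, 0, -1))
  expect_error(extract_height(dsm, roi, ground = dtm_small), "share the DSM")
})

test_that("biomass formulas evaluate over earlier traits with logging", {
  clear_run_log()
  f <- parse_formula("biomass", "0.5*height")
  expect_equal(compute_biomass(f, list(height = 1.2)), 0.6)
  expect_equal(compute_biomass(parse_formula("b", "height"),
                               list(height = 3.3)), 3.3)
  expect_true(is.na(compute_biomass(f, list(NDVI = 0.8))))
  expect_match(run_log()[length(run_log())], "undefined trait")
  expect_true(is.na(compute_biomass(f, list(height = NA_real_))))
  clear_run_log()
})

test_that("external scripts follow the last-line-numeric protocol", {
  clear_run_log()
  img <- tempfile(fileext = ".tif")
  write_raster(tiny_raster(3, 3), img)
  s1 <- generate_stub_script(tempfile(fileext = ".sh"), "constant", 2.5)
  spec1 <- external_feature_spec(s1$interpreter, s1$script)
  expect_equal(run_external_feature(spec1, img, "P1"), 2.5)
  # multi-line output: last line wins
  s2 <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo header", "echo 3.75"), s2)
  expect_equal(run_external_feature(external_feature_spec("/bin/sh", s2),
                                    img, "P1"), 3.75)
  # failure and junk output yield missing + log entries
  s3 <- generate_stub_script(tempfile(fileext = ".sh"), "fail")
  expect_true(is.na(run_external_feature(
    external_feature_spec(s3$interpreter, s3$script), img, "P2")))
  expect_match(paste(run_log(), collapse = "\n"), "exit status 1")
  s4 <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo not-a-number"), s4)
  expect_true(is.na(run_external_feature(
    external_feature_spec("/bin/sh", s4), img, "P3")))
  expect_match(paste(run_log(), collapse = "\n"), "non-numeric")
  # configuration errors surface before a batch starts
  expect_error(validate_external_spec(
    external_feature_spec("/no/such/python", s4)), "interpreter not found")
  expect_error(validate_external_spec(
    external_feature_spec("/bin/sh", "/no/such/script.py")),
    "script not found")
  expect_error(external_feature_spec("/bin/sh", s4, timeout = 0),
               "timeout")
  clear_run_log()
})

test_that("the mean-echo stub agrees with zonal_stat on the clip", {
  field <- make_small_field(tempfile(), n_rows = 1, n_cols = 2)
  ms <- load_raster(field$paths$ms)
  rois <- load_rois(field$paths$rois, id_field = "plot_id")
  clip <- clip_plot(ms, rois[[1]])
  # single-band clip for the stub
  one <- raster_grid(clip$values[, , 5], clip$geotransform,
                     crs = clip$crs, datatype = "Float64")
  p <- tempfile(fileext = ".tif")
  write_raster(one, p)
  stub <- generate_stub_script(tempfile(fileext = ".py"), "mean")
  got <- run_external_feature(
    external_feature_spec(stub$interpreter, stub$script), p, "P0001")
  expect_equal(got, zonal_stat(one, "mean")$value, tolerance = 1e-9)
})

test_that("extract_plot runs a strategy and matches closed-form truth", {
  field <- make_small_field(tempfile(), n_rows = 2, n_cols = 3)
  truth <- field$truth
  ms <- load_raster(field$paths$ms)
  rgb <- load_raster(field$paths$rgb)
  dsm <- load_raster(field$paths$dsm)
  rois <- load_rois(field$paths$rois, id_field = "plot_id")
  panels <- load_panels(field$paths$panels_shp, field$paths$panels_csv)
  bm <- default_band_map("MS")
  cal <- apply_calibration(ms, fit_empirical_line(ms, bm, panels), bm)
  stub <- generate_stub_script(tempfile(fileext = ".sh"), "constant", 7)
  strat <- extraction_strategy(list(
    feature_formula("NDVI", get_preset("NDVI", "MS"), source = "ms"),
    feature_formula("EXG", get_preset("EXG", "RGB"), source = "rgb"),
    feature_height("height", ground = truth$ground_elev),
    feature_biomass("biomass", parse_formula("biomass", "0.5*height")),
    feature_external("stub", external_feature_spec(stub$interpreter,
                                                   stub$script))))
  wk <- tempfile()
  images <- list(ms = cal, rgb = rgb, dsm = dsm)
  for (i in seq_along(rois)) {
    rec <- extract_plot(images, rois[[i]], strat, date = "2024-07-01",
                        workdir = wk)
    tp <- truth$plots[i, ]
    expect_equal(rec$values[["NDVI"]], tp$NDVI, tolerance = 1e-9)
    expect_equal(rec$values[["EXG"]], tp$EXG, tolerance = 1e-9)
    expect_equal(rec$values[["height"]], tp$height, tolerance = 1e-9)
    expect_equal(rec$values[["biomass"]], 0.5 * tp$height,
                 tolerance = 1e-9)
    expect_equal(rec$values[["stub"]], 7)
    expect_gte(min(rec$pixel_counts[c("NDVI", "EXG")]), 25)
  }
  # clips for external features are retained as {plot_id}.tif
  expect_true(all(file.exists(file.path(wk, paste0(
    truth$plots$plot_id, ".tif")))))
  # empty strategy: record with id/date only
  rec0 <- extract_plot(images, rois[[1]], extraction_strategy(list()),
                       date = "2024-07-01")
  expect_identical(rec0$plot_id, "P0001")
  expect_length(rec0$values, 0)
  # missing image role enumerates blocked features
  expect_error(extract_plot(list(ms = cal), rois[[1]], strat),
               "missing image role.*EXG")
})

test_that("formula-only features commute and band-mean mode differs only
          for nonlinear formulas", {
  field <- make_small_field(tempfile(), n_rows = 1, n_cols = 2,
                            noise_dn = 3)
  ms <- load_raster(field$paths$ms)
  rois <- load_rois(field$paths$rois, id_field = "plot_id")
  f1 <- feature_formula("NDVI", get_preset("NDVI", "MS"), source = "ms")
  f2 <- feature_formula("RVI", get_preset("RVI", "MS"), source = "ms")
  f3 <- feature_formula("DVI", get_preset("DVI", "MS"), source = "ms")
  a <- extract_plot(list(ms = ms), rois[[1]],
                    extraction_strategy(list(f1, f2, f3)))
  b <- extract_plot(list(ms = ms), rois[[1]],
                    extraction_strategy(list(f3, f1, f2)))
  expect_equal(a$values[sort(names(a$values))],
               b$values[sort(names(b$values))])
  # band_mean mode: equal for the linear DVI, different for NDVI on noisy
  # pixels
  dvi_px <- extract_plot(list(ms = ms), rois[[1]],
                         extraction_strategy(list(f3)))
  f3m <- feature_formula("DVI", get_preset("DVI", "MS"), source = "ms",
                         eval_mode = "band_mean")
  dvi_bm <- extract_plot(list(ms = ms), rois[[1]],
                         extraction_strategy(list(f3m)))
  expect_equal(dvi_px$values[["DVI"]], dvi_bm$values[["DVI"]],
               tolerance = 1e-12)
  f1m <- feature_formula("NDVI", get_preset("NDVI", "MS"), source = "ms",
                         eval_mode = "band_mean")
  ndvi_bm <- extract_plot(list(ms = ms), rois[[1]],
                          extraction_strategy(list(f1m)))
  expect_false(isTRUE(all.equal(a$values[["NDVI"]],
                                ndvi_bm$values[["NDVI"]],
                                tolerance = 1e-12)))
})

test_that("strategy validation enforces unique names and biomass ordering", {
  f <- feature_formula("NDVI", get_preset("NDVI", "MS"))
  expect_error(extraction_strategy(list(f, f)), "duplicate feature names")
  bm <- feature_biomass("biomass", parse_formula("biomass", "0.5*height"))
  expect_error(extraction_strategy(list(bm)),
               "not defined earlier.*height")
  h <- feature_height("height", ground = 10)
  expect_s3_class(extraction_strategy(list(h, bm)), "extraction_strategy")
})

test_that("per-pixel NDVI converges to the closed form as noise shrinks", {
  # delta-method: with per-pixel DN noise sigma, the plot-mean NDVI error
  # is O(sigma / sqrt(n_pixels)); at sigma = 0 it is exact.
  errs <- vapply(c(4, 1), function(sigma) {
    field <- make_small_field(tempfile(), n_rows = 1, n_cols = 3,
                              noise_dn = sigma, seed = 77, gsd = 5)
    ms <- load_raster(field$paths$ms)
    rois <- load_rois(field$paths$rois, id_field = "plot_id")
    panels <- load_panels(field$paths$panels_shp, field$paths$panels_csv)
    bmms <- default_band_map("MS")
    cal <- apply_calibration(ms, fit_empirical_line(ms, bmms, panels), bmms)
    strat <- extraction_strategy(list(
      feature_formula("NDVI", get_preset("NDVI", "MS"), source = "ms")))
    max(vapply(seq_along(rois), function(i) {
      rec <- extract_plot(list(ms = cal), rois[[i]], strat)
      abs(rec$values[["NDVI"]] - field$truth$plots$NDVI[i])
    }, numeric(1)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # 3-sigma delta-method bound at sigma = 1 DN: d(NDVI)/d(band) ~ 2/(nir+r)
  # in reflectance units (gain 0.001/DN), 900 pixels per plot
  bound <- 3 * 2 / 0.35 * 0.001 * 1 / sqrt(900) * sqrt(2)
  expect_lt(errs[2], bound)
})
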