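# geodata_io: GeoTIFF read/write, band maps, pixel-center clipping.

test_that("write/read round-trips values, geotransform, crs and nodata", {
  set.seed(11)
  for (dt in c("Float64", "Float32", "Int32", "UInt16", "UInt8")) {
    h <- 7; w <- 5; nb <- if (dt == "Float64") 3 else 1
    v <- array(switch(dt,
                      Float64 = runif(h * w * nb) * 100,
                      Float32 = round(runif(h * w) * 100, 2),
                      Int32 = sample(-1e6:1e6, h * w),
                      UInt16 = sample(0:65535, h * w),
                      UInt8 = sample(0:255, h * w, replace = TRUE)),
               dim = c(h, w, nb))
    nodata <- if (dt %in% c("Float64", "Float32")) -9999 else NA
    if (dt == "Float64") v[3, 2, ] <- NA
    r <- raster_grid(v, c(500000, 0.25, 0, 3370000, 0, -0.25),
                     crs = "EPSG:32649", nodata = nodata, datatype = dt)
    path <- tempfile(fileext = ".tif")
    write_raster(r, path)
    r2 <- load_raster(path)
    if (dt == "Float32") {
      expect_equal(r2$values, r$values, tolerance = 1e-6)
    } else {
      expect_identical(r2$values, r$values)
    }
    expect_identical(r2$geotransform, r$geotransform)
    expect_identical(r2$crs, "EPSG:32649")
    expect_equal(raster_gsd(r2), 25)
  }
})

test_that("our GeoTIFFs agree with an independent reader (tifffile)", {
  py <- expect_python()
  set.seed(12)
  r <- tiny_raster(6, 9, bands = 2)
  path <- tempfile(fileext = ".tif")
  write_raster(r, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, tifffile, numpy as np",
    "a = tifffile.imread(sys.argv[1]).astype(float)",
    "print(a.shape)",
    "print(repr(float(a.sum())))"), script)
  out <- system2(py, shQuote(c(script, path)), stdout = TRUE)
  expect_equal(out[1], "(6, 9, 2)")
  expect_equal(as.numeric(out[2]), sum(r$values))
})

test_that("a TIFF written by an independent writer loads correctly", {
  py <- expect_python()
  path <- tempfile(fileext = ".tif")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, tifffile",
    "a = np.arange(20, dtype=np.float64).reshape(4, 5)",
    "tifffile.imwrite(sys.argv[1], a,",
    "    extratags=[(33550, 'd', 3, (0.5, 0.5, 0.0)),",
    "               (33922, 'd', 6, (0, 0, 0, 100.0, 200.0, 0))])"),
    script)
  expect_equal(system2(py, shQuote(c(script, path))), 0L)
  r <- load_raster(path)
  expect_equal(dim(r$values), c(4L, 5L, 1L))
  expect_equal(as.vector(t(r$values[, , 1])), as.double(0:19))
  expect_equal(r$geotransform, c(100, 0.5, 0, 200, 0, -0.5))
})

test_that("band maps validate indices and sensor requirements", {
  r3 <- tiny_raster(4, 4, bands = 3)
  expect_silent(load_raster(write_raster(r3, tempfile(fileext = ".tif")),
                            default_band_map("RGB")))
  bm5 <- default_band_map("MS")
  path <- tempfile(fileext = ".tif")
  write_raster(r3, path)
  expect_error(load_raster(path, bm5), "band index [45] > 3 bands")
  expect_error(load_raster(path, band_map("OTHER", nir = 5)),
               "band index 5 > 3 bands")
  expect_error(band_map("MS", r = 1, g = 2, b = 3), "requires bands")
  expect_error(band_map("RGB", r = 1, g = 1, b = 2), "injective")
  expect_error(band_map("RGB", r = 1, g = 2, b = 3, x = 4),
               "unknown canonical band")
})

test_that("missing georeferencing and unreadable files error by name", {
  expect_error(load_raster("no/such/file.tif"), "not found")
  py <- expect_python()
  path <- tempfile(fileext = ".tif")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, tifffile",
    "tifffile.imwrite(sys.argv[1], np.zeros((3, 3)))"), script)
  system2(py, shQuote(c(script, path)))
  expect_error(load_raster(path), "no georeferencing")
})

test_that("aligned rectangular ROI clips exactly with no nodata", {
  r <- tiny_raster(8, 8, origin = c(0, 8))  # pixel = 1, extent x 0..8 y 0..8
  roi <- square_roi("A", 2, 6, 4)           # covers cols 3..6, rows 3..6
  clip <- clip_plot(r, roi)
  expect_equal(dim(clip$values), c(4L, 4L, 1L))
  expect_false(anyNA(clip$values))
  expect_equal(attr(clip, "n_inside"), 16L)
  expect_equal(clip$geotransform[c(1, 4)], c(2, 6))
  # sub-grid values match direct indexing
  expect_equal(clip$values[, , 1], r$values[3:6, 3:6, 1])
})

test_that("triangular ROI mask equals the brute-force oracle", {
  r <- tiny_raster(10, 10, origin = c(0, 10))
  tri <- plot_roi("T", rbind(c(0.2, 9.7), c(9.5, 8.9), c(4.2, 0.4)),
                  crs = "EPSG:32649")
  clip <- clip_plot(r, tri)
  # compare against exhaustive oracle over the full raster
  full <- oracle_mask(r, tri)
  clipped_full <- matrix(FALSE, 10, 10)
  d <- dim(clip$values)
  row0 <- round((r$geotransform[4] - clip$geotransform[4]) /
                  -r$geotransform[6])
  col0 <- round((clip$geotransform[1] - r$geotransform[1]) /
                  r$geotransform[2])
  clipped_full[row0 + seq_len(d[1]), col0 + seq_len(d[2])] <-
    !is.na(clip$values[, , 1])
  expect_identical(clipped_full, full)
})

test_that("pixel-center containment matches the oracle on random polygons", {
  set.seed(99)
  r <- tiny_raster(16, 16, origin = c(0, 16))
  for (k in 1:50) {
    poly <- random_polygon(center = runif(2, 3, 13), radius = runif(1, 1, 6),
                           n_vertices = sample(3:8, 1))
    roi <- plot_roi(paste0("R", k), poly, crs = "EPSG:32649")
    clip <- suppressWarnings(clip_plot(r, roi))
    d <- dim(clip$values)
    row0 <- round((r$geotransform[4] - clip$geotransform[4]))
    col0 <- round((clip$geotransform[1] - r$geotransform[1]))
    got <- matrix(FALSE, 16, 16)
    got[row0 + seq_len(d[1]), col0 + seq_len(d[2])] <-
      !is.na(clip$values[, , 1])
    expect_identical(got, oracle_mask(r, roi))
  }
})

test_that("clip agrees with shapely's closed-boundary containment", {
  py <- expect_python()
  set.seed(7)
  r <- tiny_raster(12, 12, origin = c(0, 12))
  poly <- random_polygon(center = c(6, 6), radius = 5, n_vertices = 7)
  roi <- plot_roi("S", poly, crs = "EPSG:32649")
  mask_r <- oracle_mask(r, roi)
  script <- tempfile(fileext = ".py")
  poly_txt <- paste(apply(poly, 1, paste, collapse = ","), collapse = ";")
  writeLines(c(
    "import sys",
    "from shapely.geometry import Polygon, Point",
    "ring = [tuple(map(float, p.split(','))) for p in sys.argv[1].split(';')]",
    "poly = Polygon(ring)",
    "out = []",
    "for i in range(12):",
    "    y = 12 - (i + 0.5)",
    "    row = ''.join('1' if poly.intersects(Point(j + 0.5, y)) else '0'",
    "                  for j in range(12))",
    "    out.append(row)",
    "print('\\n'.join(out))"), script)
  out <- system2(py, shQuote(c(script, poly_txt)), stdout = TRUE)
  mask_py <- do.call(rbind, lapply(out, function(s)
    as.integer(strsplit(s, "")[[1]]) == 1L))
  expect_identical(mask_r, mask_py)
})

test_that("clipping is idempotent and honors contracts", {
  r <- tiny_raster(10, 10, origin = c(0, 10))
  tri <- plot_roi("T", rbind(c(1, 9), c(8, 8), c(5, 1)), crs = "EPSG:32649")
  c1 <- clip_plot(r, tri)
  c2 <- clip_plot(c1, tri)
  expect_identical(c2$values, c1$values)
  expect_identical(c2$geotransform, c1$geotransform)
  # CRS mismatch: explicit error, no silent reprojection
  tri_bad <- plot_roi("T", tri$polygon, crs = "EPSG:4326")
  expect_error(clip_plot(r, tri_bad), "CRS mismatch")
  # disjoint ROI
  far <- square_roi("F", 100, 100, 2)
  expect_error(clip_plot(r, far), "does not intersect")
  # zero pixel centers inside: warning + flag
  sliver <- plot_roi("s", rbind(c(0.9, 9.9), c(1.1, 9.9), c(1.0, 9.8)),
                     crs = "EPSG:32649")
  expect_warning(cl <- clip_plot(r, sliver), "no pixel centers")
  expect_true(isTRUE(attr(cl, "empty_clip")))
})

test_that("write-clip-write composition loads consistently", {
  r <- tiny_raster(8, 8, origin = c(0, 8), bands = 2)
  p1 <- tempfile(fileext = ".tif")
  write_raster(r, p1)
  clip <- clip_plot(load_raster(p1), square_roi("A", 1, 7, 3))
  p2 <- tempfile(fileext = ".tif")
  write_raster(clip, p2)
  back <- load_raster(p2)
  expect_identical(back$values, clip$values)
  expect_identical(back$geotransform, clip$geotransform)
})
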