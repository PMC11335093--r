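#' Georeferenced multiband raster
#'
#' The package's raster container: a numeric array of `height x width x
#' n_bands` cell values (with `NA` marking missing/nodata pixels), a
#' GDAL-style geotransform mapping pixel indices to world coordinates, a CRS
#' identifier, and the on-disk nodata sentinel and sample type.
#'
#' The geotransform is the 6-vector `(x0, dx, 0, y0, 0, -dy)`: the world
#' x-coordinate of the top-left CORNER of pixel (1,1) is `x0`, x grows with
#' column at `dx` per pixel, and y shrinks with row at `dy` per pixel (north
#' up). Only axis-aligned transforms are supported.
#'
#' @param values numeric matrix (single band) or `[h, w, bands]` array;
#'   `NA` marks missing pixels.
#' @param geotransform numeric length-6 as above.
#' @param crs CRS identifier string, e.g. `"EPSG:32649"`, or `NA`.
#' @param nodata on-disk sentinel written for `NA` cells, or `NA` to pick a
#'   type default at write time.
#' @param datatype on-disk sample type: one of `"UInt8"`, `"UInt16"`,
#'   `"Int16"`, `"Int32"`, `"Float32"`, `"Float64"`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, geotransform, crs = NA_character_,
                        nodata = NA_real_, datatype = "Float64") {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3, length(geotransform) == 6)
  if (any(dim(values) < 1L)) stop("raster dimensions must be positive")
  if (geotransform[2] == 0 || geotransform[6] == 0)
    stop("geotransform has zero pixel size")
  if (geotransform[3] != 0 || geotransform[5] != 0)
    stop("rotated geotransforms are not supported")
  storage.mode(values) <- "double"
  structure(list(values = values, geotransform = as.double(geotransform),
                 crs = crs, nodata = nodata, datatype = datatype),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d pixels, %d band(s)\n", d[2], d[1], d[3]))
  cat(sprintf("  origin (%.6g, %.6g), pixel %.6g x %.6g, gsd %.4g cm\n",
              x$geotransform[1], x$geotransform[4], x$geotransform[2],
              -x$geotransform[6], raster_gsd(x)))
  cat(sprintf("  crs %s, nodata %s, %s\n", x$crs,
              format(x$nodata), x$datatype))
  invisible(x)
}

#' @rdname raster_grid
#' @param x a `raster_grid`.
#' @export
n_bands <- function(x) dim(x$values)[3]

#' Ground sampling distance in cm per pixel
#'
#' Derived from the geotransform, assuming world units are metres.
#'
#' @param x a `raster_grid`.
#' @return numeric scalar, cm/pixel.
#' @export
raster_gsd <- function(x) abs(x$geotransform[2]) * 100

#' World coordinates of pixel centers
#'
#' @param x a `raster_grid`.
#' @param rows,cols integer indices (1-based). Defaults to all.
#' @return list with numeric vectors `x` (per column) and `y` (per row).
#' @export
pixel_centers <- function(x, rows = seq_len(dim(x$values)[1]),
                          cols = seq_len(dim(x$values)[2])) {
  gt <- x$geotransform
  list(x = gt[1] + (cols - 0.5) * gt[2],
       y = gt[4] + (rows - 0.5) * gt[6])
}

#' Raster extent in world coordinates
#' @param x a `raster_grid`.
#' @return named numeric: xmin, ymin, xmax, ymax.
#' @export
raster_extent <- function(x) {
  gt <- x$geotransform
  d <- dim(x$values)
  c(xmin = gt[1], ymin = gt[4] + d[1] * gt[6],
    xmax = gt[1] + d[2] * gt[2], ymax = gt[4])
}

#' Sensor band map
#'
#' Binds the canonical band variable names used by trait formulas (`r`,
#' `g`, `b`, `re`, `nir`) to 1-based band indices of a raster. An RGB
#' sensor must bind at least r, g, b; a multispectral (MS) sensor must bind
#' all five.
#'
#' @param sensor `"RGB"`, `"MS"`, or `"OTHER"`.
#' @param ... named 1-based band indices, e.g. `r = 3, g = 2, b = 1`.
#' @return object of class `band_map`.
#' @examples
#' band_map("MS", b = 1, g = 2, r = 3, re = 4, nir = 5)
#' @export
band_map <- function(sensor = c("RGB", "MS", "OTHER"), ...) {
  sensor <- match.arg(sensor)
  bindings <- c(...)
  if (length(bindings) == 0) stop("band_map needs at least one binding")
  bad <- setdiff(names(bindings), c("r", "g", "b", "re", "nir"))
  if (length(bad))
    stop("unknown canonical band name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(bindings))
    stop("band bindings must be injective (two names share a band index)")
  need <- switch(sensor, RGB = c("r", "g", "b"),
                 MS = c("r", "g", "b", "re", "nir"), character())
  missing <- setdiff(need, names(bindings))
  if (length(missing))
    stop("sensor ", sensor, " requires bands: ",
         paste(missing, collapse = ", "))
  bindings <- stats::setNames(as.integer(bindings), names(bindings))
  structure(list(sensor = sensor, bindings = bindings),
            class = "band_map")
}

#' Default band maps for common sensor layouts
#' @param sensor `"RGB"` (bands r,g,b = 1,2,3) or `"MS"`
#'   (b,g,r,re,nir = 1,2,3,4,5 — the RedEdge band order).
#' @return a [band_map()].
#' @export
default_band_map <- function(sensor = c("RGB", "MS")) {
  sensor <- match.arg(sensor)
  if (sensor == "RGB") band_map("RGB", r = 1, g = 2, b = 3)
  else band_map("MS", b = 1, g = 2, r = 3, re = 4, nir = 5)
}

validate_band_map <- function(band_map, raster, path = "raster") {
  nb <- n_bands(raster)
  over <- band_map$bindings > nb
  if (any(over)) {
    nm <- names(band_map$bindings)[which(over)[1]]
    stop(sprintf("band index %d > %d bands (band '%s' of %s)",
                 band_map$bindings[which(over)[1]], nb, nm, path))
  }
  invisible(TRUE)
}

#' Read a georeferenced TIFF
#'
#' Reads an uncompressed strip-based GeoTIFF (the format this package and
#' common UAV processing chains write). Nodata cells become `NA`.
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @param band_map optional [band_map()]; validated against the band count.
#' @return a [raster_grid()].
#' @export
load_raster <- function(path, band_map = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  raw <- .tiff_read(path)
  vals <- raw$values
  if (!is.na(raw$nodata)) vals[vals == raw$nodata] <- NA_real_
  grid <- raster_grid(vals, raw$geotransform, crs = raw$crs,
                      nodata = raw$nodata, datatype = raw$datatype)
  if (!is.null(band_map)) validate_band_map(band_map, grid, path)
  grid
}

.default_nodata <- function(datatype) {
  switch(datatype,
         Float32 = -3.4028234663852886e+38,
         Float64 = -1.7e+308,
         Int32 = -2147483648,
         Int16 = -32768,
         stop("raster has missing pixels but no nodata value is set for ",
              "integer type ", datatype))
}

#' Write a raster_grid to GeoTIFF
#'
#' `load_raster(write_raster(x, path))` reproduces values, geotransform,
#' CRS and nodata. `NA` cells are stored as the nodata sentinel (a type
#' default is chosen if none is set).
#'
#' @param raster a [raster_grid()].
#' @param path destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  vals <- raster$values
  nodata <- raster$nodata
  if (anyNA(vals)) {
    if (is.na(nodata)) nodata <- .default_nodata(raster$datatype)
    vals[is.na(vals)] <- nodata
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (missing directory): ", dir)
  .tiff_write(path, vals, raster$geotransform, crs = raster$crs,
              nodata = nodata, datatype = raster$datatype)
  invisible(path)
}

#' Clip a raster to a plot ROI
#'
#' Returns the sub-raster covering the ROI's bounding box, with every pixel
#' whose CENTER falls outside the polygon set to `NA`. Pixel centers lying
#' exactly on the polygon boundary count as inside. The clip's geotransform
#' is updated so it stays georeferenced; no resampling or reprojection is
#' performed.
#'
#' @param raster a [raster_grid()].
#' @param roi a [plot_roi()] in the same CRS.
#' @return a `raster_grid` with attribute `n_inside` (count of pixel
#'   centers inside the polygon) and, when that count is zero, attribute
#'   `empty_clip = TRUE` plus a warning.
#' @export
clip_plot <- function(raster, roi) {
  if (!is.na(raster$crs) && !is.na(roi$crs) &&
      !identical(raster$crs, roi$crs))
    stop("CRS mismatch: raster is ", raster$crs, ", ROI '", roi$plot_id,
         "' is ", roi$crs, " (no silent reprojection)")
  gt <- raster$geotransform
  d <- dim(raster$values)
  ext <- raster_extent(raster)
  ring <- roi$polygon$outer
  bb <- c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
  if (bb[1] >= ext["xmax"] || bb[3] <= ext["xmin"] ||
      bb[2] >= ext["ymax"] || bb[4] <= ext["ymin"])
    stop("ROI '", roi$plot_id, "' does not intersect the raster extent")

  # pixel index range covering the bbox (clamped to the raster)
  col0 <- max(1L, floor((bb[1] - gt[1]) / gt[2]) + 1L)
  col1 <- min(d[2], ceiling((bb[3] - gt[1]) / gt[2]))
  row0 <- max(1L, floor((bb[4] - gt[4]) / gt[6]) + 1L)
  row1 <- min(d[1], ceiling((bb[2] - gt[4]) / gt[6]))
  if (col0 > col1 || row0 > row1)
    stop("ROI '", roi$plot_id, "' does not intersect the raster extent")

  sub <- raster$values[row0:row1, col0:col1, , drop = FALSE]
  ctr <- pixel_centers(raster, rows = row0:row1, cols = col0:col1)
  grid_xy <- expand.grid(y = ctr$y, x = ctr$x)  # row varies fastest
  inside <- point_in_polygon(grid_xy$x, grid_xy$y, roi$polygon)
  mask <- matrix(inside, nrow = length(ctr$y), ncol = length(ctr$x))
  for (b in seq_len(dim(sub)[3])) {
    band <- sub[, , b]
    band[!mask] <- NA_real_
    sub[, , b] <- band
  }
  new_gt <- gt
  new_gt[1] <- gt[1] + (col0 - 1L) * gt[2]
  new_gt[4] <- gt[4] + (row0 - 1L) * gt[6]
  out <- raster_grid(sub, new_gt, crs = raster$crs, nodata = raster$nodata,
                     datatype = raster$datatype)
  attr(out, "n_inside") <- sum(mask)
  if (sum(mask) == 0L) {
    attr(out, "empty_clip") <- TRUE
    warning("ROI '", roi$plot_id, "' contains no pixel centers",
            call. = FALSE)
  }
  out
}
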