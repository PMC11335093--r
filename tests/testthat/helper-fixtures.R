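# Shared fixtures and independent oracles.

# Independent point-in-polygon oracle: scalar winding-style crossing count,
# written as a plain per-point loop (structured differently from the
# package's vectorised implementation). Closed boundary: on-edge is inside.
oracle_point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    # on-segment check
    d <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (d == 0 && x >= min(xi, xj) && x <= max(xi, xj) &&
        y >= min(yi, yj) && y <= max(yi, yj)) return(TRUE)
    if ((yi > y) != (yj > y)) {
      x_cross <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive per-pixel mask of a raster by an ROI, using the oracle test.
oracle_mask <- function(raster, roi) {
  d <- dim(raster$values)
  ctr <- pixel_centers(raster)
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      mask[i, j] <- oracle_point_in_ring(ctr$x[j], ctr$y[i],
                                         roi$polygon$outer)
  mask
}

# Random simple polygon: points on a jittered circle, ordered by angle.
random_polygon <- function(center, radius, n_vertices = 5L) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.3 * radius, radius)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# Tiny test raster: values 1..(h*w) band 1, reversed band 2 if asked.
tiny_raster <- function(h = 8, w = 8, bands = 1, origin = c(100, 200),
                        px = 1, crs = "EPSG:32649") {
  v <- array(NA_real_, dim = c(h, w, bands))
  for (b in seq_len(bands))
    v[, , b] <- matrix(seq_len(h * w) * b, h, w, byrow = TRUE)
  raster_grid(v, c(origin[1], px, 0, origin[2], 0, -px), crs = crs)
}

square_roi <- function(id, x0, y0, size, crs = "EPSG:32649") {
  plot_roi(id, rbind(c(x0, y0), c(x0 + size, y0),
                     c(x0 + size, y0 - size), c(x0, y0 - size)), crs = crs)
}

# Small synthetic field shared by extraction/batch tests.
make_small_field <- function(dir, n_rows = 2, n_cols = 5, noise_dn = 0,
                             noise_dsm = 0, seed = 42, gsd = 10) {
  truth <- field_truth(n_rows = n_rows, n_cols = n_cols,
                       noise_dn = noise_dn, noise_dsm = noise_dsm,
                       seed = seed)
  paths <- generate_field(truth, gsd = gsd, out_dir = dir)
  list(truth = truth, paths = paths)
}

expect_python <- function() {
  if (!nzchar(Sys.which("python")))
    stop("python interpreter unexpectedly absent from PATH")
  Sys.which("python")
}

# printed "R mean" / "Efficiency" cells of the 16-row performance table
printed_performance <- function() {
  data.frame(
    test = paste0("T", 1:16),
    mean_2dp = c(8.25, 12.50, 7.41, 12.36, 4.10, 6.07, 25.84, 42.09,
                 15.52, 24.75, 17.40, 26.50, 6.44, 10.55, 43.99, 74.19),
    eff_2dp = c(586.90, 580.95, 1632.93, 1566.77, 1464.61, 1481.89,
                580.57, 570.16, 515.35, 484.91, 1149.43, 1207.55,
                1551.99, 1421.35, 568.31, 539.18))
}
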