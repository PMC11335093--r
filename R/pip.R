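#' Point-in-polygon test with a closed boundary
#'
#' Vectorised crossing-number (even-odd) containment test. Points that lie
#' exactly on a polygon edge or vertex count as inside (closed-boundary
#' convention), which makes pixel-center masking deterministic for plot
#' rectangles drawn on pixel edges.
#'
#' @param px,py numeric vectors of point coordinates (equal length).
#' @param ring two-column matrix of ring vertices in order; the closing
#'   vertex may be present or absent.
#' @return logical vector, `TRUE` where the point is inside or on the ring.
#' @keywords internal
point_in_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  # drop an explicit closing vertex
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) stop("ring must have at least 3 distinct vertices")
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  xs <- ring[, 1]; ys <- ring[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # boundary: point collinear with the segment and within its bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onseg <- cross == 0 &
      px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
    on_edge <- on_edge | onseg
    # crossing test for a rightward ray
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' @rdname point_in_ring
#' @param polygon a list with elements `outer` (ring matrix) and optionally
#'   `holes` (list of ring matrices).
#' @keywords internal
point_in_polygon <- function(px, py, polygon) {
  inside <- point_in_ring(px, py, polygon$outer)
  for (hole in polygon$holes %||% list()) {
    # points strictly inside a hole are excluded; hole boundaries stay in
    in_hole <- point_in_ring(px, py, hole) &
      !point_on_ring_boundary(px, py, hole)
    inside <- inside & !in_hole
  }
  inside
}

#' @keywords internal
point_on_ring_boundary <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  on_edge <- logical(length(px))
  xs <- ring[, 1]; ys <- ring[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onseg <- cross == 0 &
      px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
    on_edge <- on_edge | onseg
  }
  on_edge
}
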