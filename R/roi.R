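#' Plot region of interest
#'
#' A labeled polygon delimiting one experimental plot, with optional
#' attribute fields carried to/from the shapefile attribute table.
#'
#' @param plot_id unique plot label.
#' @param polygon either a two-column vertex matrix (outer ring) or a list
#'   `list(outer = matrix, holes = list(...))`.
#' @param attributes named list of scalar attributes.
#' @param crs CRS identifier string or `NA`.
#' @return object of class `plot_roi`.
#' @export
plot_roi <- function(plot_id, polygon, attributes = list(),
                     crs = NA_character_) {
  if (is.matrix(polygon)) polygon <- list(outer = polygon, holes = list())
  polygon$outer <- as.matrix(polygon$outer)
  ring <- polygon$outer
  open_ring <- if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ]))
    ring[-nrow(ring), , drop = FALSE] else ring
  if (nrow(unique(open_ring)) < 3)
    stop("ROI '", plot_id, "': ring needs >= 3 distinct vertices")
  if (abs(.ring_signed_area(ring)) == 0)
    stop("ROI '", plot_id, "': polygon has zero area")
  structure(list(plot_id = as.character(plot_id), polygon = polygon,
                 attributes = attributes, crs = crs),
            class = "plot_roi")
}

#' @export
print.plot_roi <- function(x, ...) {
  cat(sprintf("<plot_roi> '%s': %d vertices, area %.4g, crs %s\n",
              x$plot_id, nrow(x$polygon$outer),
              roi_area(x), x$crs))
  invisible(x)
}

#' Polygon area of an ROI (world units squared)
#' @param roi a [plot_roi()].
#' @export
roi_area <- function(roi) {
  a <- abs(.ring_signed_area(roi$polygon$outer))
  for (h in roi$polygon$holes %||% list()) a <- a - abs(.ring_signed_area(h))
  a
}

#' Centroid of an ROI's outer ring
#' @param roi a [plot_roi()].
#' @return numeric length 2 (x, y).
#' @export
roi_centroid <- function(roi) {
  ring <- .close_ring(roi$polygon$outer)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  c(x = sum((x[-n] + x[-1]) * cross) / (6 * a),
    y = sum((y[-n] + y[-1]) * cross) / (6 * a))
}

#' Load plot ROIs from a polygon shapefile
#'
#' One [plot_roi()] per feature, in file order. Attribute fields are carried
#' through. If `id_field` is absent (or `NULL`), sequential ids
#' `P0001, P0002, ...` are assigned.
#'
#' @param path path to the `.shp` file.
#' @param id_field attribute field holding the plot label, or `NULL`.
#' @return list of `plot_roi` objects.
#' @export
load_rois <- function(path, id_field = NULL) {
  sf <- .read_shapefile(path)
  n <- length(sf$polygons)
  att <- sf$attributes
  if (!is.null(id_field)) {
    if (!id_field %in% names(att))
      stop("id field '", id_field, "' not present in ", path)
    ids <- as.character(att[[id_field]])
    # numeric ids read from DBF may carry trailing zeros; tidy integers
    num <- suppressWarnings(as.numeric(ids))
    if (!anyNA(num) && all(num == round(num))) ids <- format(num, trim = TRUE)
  } else {
    ids <- sprintf("P%04d", seq_len(n))
  }
  dups <- unique(ids[duplicated(ids)])
  if (length(dups))
    stop("duplicate plot ids in ", path, ": ", paste(dups, collapse = ", "))
  lapply(seq_len(n), function(i) {
    attrs <- as.list(att[i, , drop = FALSE])
    plot_roi(ids[i], sf$polygons[[i]], attributes = attrs, crs = sf$crs)
  })
}

.format_label <- function(pattern, serial, row, col) {
  out <- pattern
  fill <- function(out, key, value) {
    # {key} or {key:0Nd}
    m <- regmatches(out, gregexpr(sprintf("\\{%s(:0[0-9]+d)?\\}", key), out))[[1]]
    for (tok in unique(m)) {
      spec <- sub(sprintf("\\{%s:?", key), "", sub("\\}$", "", tok))
      rep <- if (nzchar(spec)) sprintf(paste0("%", spec), value)
             else as.character(value)
      out <- gsub(tok, rep, out, fixed = TRUE)
    }
    out
  }
  out <- fill(out, "serial", serial)
  out <- fill(out, "row", row)
  fill(out, "col", col)
}

#' Replicate a template ROI over a regular grid
#'
#' Produces `n_cols * n_rows` pure translations of the template polygon:
#' copy (i, j) (0-based col i, row j) is the template shifted by
#' `(i * dx, -j * dy)` — columns march east, rows march south, matching how
#' field plot grids are laid out from a top-left template. Labels are
#' generated row-major from `label_pattern`, which may use `{serial}`,
#' `{row}` and `{col}` placeholders (with optional zero-padding such as
#' `{serial:04d}`); serial starts at 1.
#'
#' @param template a [plot_roi()].
#' @param n_cols,n_rows grid dimensions (>= 1).
#' @param dx,dy column and row pitch in world units (positive dy steps
#'   southward).
#' @param label_pattern label template, default `"P{serial:04d}"`.
#' @return list of `plot_roi` objects, row-major order.
#' @examples
#' tpl <- plot_roi("T", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' rois <- replicate_roi(tpl, n_cols = 3, n_rows = 2, dx = 5, dy = 6)
#' length(rois)  # 6
#' @export
replicate_roi <- function(template, n_cols, n_rows, dx, dy,
                          label_pattern = "P{serial:04d}") {
  if (n_cols < 1 || n_rows < 1) stop("n_cols and n_rows must be >= 1")
  out <- vector("list", n_cols * n_rows)
  serial <- 0L
  for (j in seq_len(n_rows) - 1L) {
    for (i in seq_len(n_cols) - 1L) {
      serial <- serial + 1L
      shift <- c(i * dx, -j * dy)
      poly <- list(
        outer = sweep(template$polygon$outer, 2L, -shift),
        holes = lapply(template$polygon$holes %||% list(),
                       function(h) sweep(h, 2L, -shift)))
      out[[serial]] <- plot_roi(
        .format_label(label_pattern, serial, j + 1L, i + 1L),
        poly, attributes = template$attributes, crs = template$crs)
    }
  }
  ids <- vapply(out, `[[`, character(1), "plot_id")
  if (anyDuplicated(ids))
    stop("label pattern '", label_pattern, "' produced duplicate ids; ",
         "include {serial} (or {row} and {col})")
  out
}

#' Write plot ROIs to a shapefile
#'
#' Writes `.shp`, `.shx`, `.dbf` (and `.prj` when a CRS is set). The plot id
#' is stored in field `plot_id`; further attributes become DBF fields with
#' names truncated to 10 characters (a numeric suffix resolves clashes; a
#' warning reports the mapping).
#'
#' @param rois list of [plot_roi()].
#' @param path destination `.shp` path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  if (length(rois) == 0L) stop("shapefile requires at least one feature")
  ids <- vapply(rois, `[[`, character(1), "plot_id")
  attr_names <- unique(unlist(lapply(rois, function(r) names(r$attributes))))
  attr_names <- setdiff(attr_names, "plot_id")
  df <- data.frame(plot_id = ids, stringsAsFactors = FALSE)
  for (nm in attr_names) {
    vals <- lapply(rois, function(r) r$attributes[[nm]])
    if (all(vapply(vals, function(v) is.null(v) || is.numeric(v),
                   logical(1)))) {
      df[[nm]] <- vapply(vals, function(v)
        if (is.null(v)) NA_real_ else as.double(v), numeric(1))
    } else {
      df[[nm]] <- vapply(vals, function(v)
        if (is.null(v)) NA_character_ else as.character(v), character(1))
    }
  }
  names(df) <- unname(sanitize_dbf_names(names(df)))
  crs <- rois[[1]]$crs
  .write_shapefile(path, lapply(rois, `[[`, "polygon"), df, crs = crs)
  invisible(path)
}
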