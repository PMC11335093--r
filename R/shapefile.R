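# Minimal ESRI shapefile codec (.shp/.shx/.dbf/.prj), polygon type only.
# DBF fields: C (character) and N (fixed-point numeric).

.ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2  # positive = counter-clockwise
}

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

.orient_ring <- function(ring, clockwise) {
  a <- .ring_signed_area(ring)
  if ((a < 0) != clockwise) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# --- DBF ---------------------------------------------------------------

.dbf_write <- function(path, df) {
  n_rec <- nrow(df)
  fields <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) list(name = nm, type = "N", length = 33L, dec = 16L)
    else {
      v <- as.character(v)
      len <- max(1L, min(254L, max(nchar(v, type = "bytes"), 0L)))
      list(name = nm, type = "C", length = len, dec = 0L)
    }
  })
  rec_len <- 1L + sum(vapply(fields, `[[`, integer(1), "length"))
  hdr_len <- 32L + 32L * length(fields) + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(3L), con, size = 1L)
  d <- as.integer(c(126, 1, 1))  # last-update date; value irrelevant
  writeBin(d, con, size = 1L)
  writeBin(as.integer(n_rec), con, size = 4L, endian = "little")
  writeBin(as.integer(hdr_len), con, size = 2L, endian = "little")
  writeBin(as.integer(rec_len), con, size = 2L, endian = "little")
  writeBin(raw(20L), con)
  for (f in fields) {
    nm <- charToRaw(substr(f$name, 1L, 10L))
    writeBin(c(nm, raw(11L - length(nm))), con)
    writeBin(charToRaw(f$type), con)
    writeBin(raw(4L), con)
    writeBin(as.integer(f$length), con, size = 1L)
    writeBin(as.integer(f$dec), con, size = 1L)
    writeBin(raw(14L), con)
  }
  writeBin(as.raw(0x0D), con)
  for (i in seq_len(n_rec)) {
    writeBin(as.raw(0x20), con)  # not deleted
    for (f in fields) {
      v <- df[[f$name]][i]
      if (f$type == "N") {
        s <- if (is.na(v)) strrep(" ", f$length)
             else formatC(v, format = "f", digits = f$dec,
                          width = f$length)
        if (nchar(s) > f$length) s <- strrep("*", f$length)  # overflow
        s <- formatC(s, width = f$length)
      } else {
        s <- if (is.na(v)) "" else as.character(v)
        s <- formatC(s, width = -f$length)  # left-justified
        s <- substr(s, 1L, f$length)
      }
      writeBin(charToRaw(s), con)
    }
  }
  writeBin(as.raw(0x1A), con)
  invisible(path)
}

.dbf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "integer", size = 1L)           # version
  readBin(con, "integer", n = 3L, size = 1L)   # date
  n_rec <- readBin(con, "integer", size = 4L, endian = "little")
  hdr_len <- readBin(con, "integer", size = 2L, signed = FALSE,
                     endian = "little")
  rec_len <- readBin(con, "integer", size = 2L, signed = FALSE,
                     endian = "little")
  readBin(con, "raw", n = 20L)
  n_fields <- (hdr_len - 33L) %/% 32L
  fields <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    nm_raw <- readBin(con, "raw", n = 11L)
    nm <- rawToChar(nm_raw[nm_raw != as.raw(0)])
    type <- rawToChar(readBin(con, "raw", n = 1L))
    readBin(con, "raw", n = 4L)
    len <- readBin(con, "integer", size = 1L, signed = FALSE)
    dec <- readBin(con, "integer", size = 1L, signed = FALSE)
    readBin(con, "raw", n = 14L)
    fields[[i]] <- list(name = nm, type = type, length = len, dec = dec)
  }
  seek(con, hdr_len)
  cols <- lapply(fields, function(f)
    if (f$type == "N") rep(NA_real_, n_rec) else rep(NA_character_, n_rec))
  names(cols) <- vapply(fields, `[[`, character(1), "name")
  for (r in seq_len(n_rec)) {
    readBin(con, "raw", n = 1L)  # deletion flag
    for (i in seq_len(n_fields)) {
      f <- fields[[i]]
      s <- rawToChar(readBin(con, "raw", n = f$length))
      s <- trimws(s)
      if (f$type == "N") {
        cols[[i]][r] <- if (nzchar(s)) suppressWarnings(as.numeric(s))
                        else NA_real_
      } else cols[[i]][r] <- s
    }
  }
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

# --- SHP / SHX ---------------------------------------------------------

.shp_header <- function(con, file_len_words, bbox) {
  writeBin(as.integer(9994L), con, size = 4L, endian = "big")
  writeBin(integer(5L), con, size = 4L, endian = "big")
  writeBin(as.integer(file_len_words), con, size = 4L, endian = "big")
  writeBin(as.integer(1000L), con, size = 4L, endian = "little")
  writeBin(as.integer(5L), con, size = 4L, endian = "little")  # polygon
  writeBin(as.double(bbox), con, size = 8L, endian = "little")
  writeBin(numeric(4L), con, size = 8L, endian = "little")     # z/m ranges
}

.polygon_rings <- function(polygon) {
  outer <- .orient_ring(.close_ring(polygon$outer), clockwise = TRUE)
  holes <- lapply(polygon$holes %||% list(), function(h)
    .orient_ring(.close_ring(h), clockwise = FALSE))
  c(list(outer), holes)
}

.write_shapefile <- function(path, polygons, attributes, crs = NA_character_) {
  if (length(polygons) == 0L)
    stop("shapefile requires at least one feature")
  base <- sub("\\.shp$", "", path)
  ring_sets <- lapply(polygons, .polygon_rings)
  contents <- lapply(ring_sets, function(rings) {
    pts <- do.call(rbind, rings)
    n_parts <- length(rings)
    n_pts <- nrow(pts)
    starts <- cumsum(c(0L, vapply(rings, nrow, integer(1))))[seq_len(n_parts)]
    bbox <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
    list(bbox = bbox, n_parts = n_parts, n_pts = n_pts, starts = starts,
         pts = pts,
         length_words = (4L + 32L + 8L + n_parts * 4L + n_pts * 16L) / 2L)
  })
  all_pts <- do.call(rbind, lapply(contents, `[[`, "pts"))
  bbox <- c(min(all_pts[, 1]), min(all_pts[, 2]),
            max(all_pts[, 1]), max(all_pts[, 2]))
  rec_words <- vapply(contents, `[[`, numeric(1), "length_words")
  shp_len <- 50L + sum(rec_words + 4L)

  con <- file(paste0(base, ".shp"), "wb")
  .shp_header(con, shp_len, bbox)
  for (i in seq_along(contents)) {
    ct <- contents[[i]]
    writeBin(as.integer(i), con, size = 4L, endian = "big")
    writeBin(as.integer(ct$length_words), con, size = 4L, endian = "big")
    writeBin(as.integer(5L), con, size = 4L, endian = "little")
    writeBin(as.double(ct$bbox), con, size = 8L, endian = "little")
    writeBin(as.integer(ct$n_parts), con, size = 4L, endian = "little")
    writeBin(as.integer(ct$n_pts), con, size = 4L, endian = "little")
    writeBin(as.integer(ct$starts), con, size = 4L, endian = "little")
    writeBin(as.double(t(ct$pts)), con, size = 8L, endian = "little")
  }
  close(con)

  con <- file(paste0(base, ".shx"), "wb")
  .shp_header(con, 50L + 4L * length(contents), bbox)
  offset <- 50L
  for (i in seq_along(contents)) {
    writeBin(as.integer(offset), con, size = 4L, endian = "big")
    writeBin(as.integer(rec_words[i]), con, size = 4L, endian = "big")
    offset <- offset + 4L + rec_words[i]
  }
  close(con)

  .dbf_write(paste0(base, ".dbf"), attributes)
  if (!is.na(crs)) {
    m <- regmatches(crs, regexpr("[0-9]+$", crs))
    code <- if (length(m)) m else ""
    wkt <- sprintf(
      'PROJCS["%s",GEOGCS["GCS_unknown",DATUM["D_unknown",SPHEROID["s",6378137,298.257223563]],PRIMEM["Greenwich",0],UNIT["Degree",0.0174532925199433]],PROJECTION["Transverse_Mercator"],UNIT["Meter",1],AUTHORITY["EPSG","%s"]]',
      crs, code)
    writeLines(wkt, paste0(base, ".prj"))
  }
  invisible(path)
}

.read_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path)
  shp <- paste0(base, ".shp")
  if (!file.exists(shp)) stop("shapefile not found: ", shp)
  con <- file(shp, "rb")
  on.exit(close(con))
  readBin(con, "integer", size = 4L, endian = "big")       # file code
  readBin(con, "integer", n = 5L, size = 4L, endian = "big")
  file_len <- readBin(con, "integer", size = 4L, endian = "big")
  readBin(con, "integer", size = 4L, endian = "little")    # version
  shape_type <- readBin(con, "integer", size = 4L, endian = "little")
  if (shape_type != 5L)
    stop("only polygon shapefiles are supported (shape type ",
         shape_type, " in ", shp, ")")
  readBin(con, "numeric", n = 8L, size = 8L, endian = "little")
  polygons <- list()
  words_read <- 50L
  while (words_read < file_len) {
    readBin(con, "integer", size = 4L, endian = "big")     # record number
    rec_words <- readBin(con, "integer", size = 4L, endian = "big")
    rtype <- readBin(con, "integer", size = 4L, endian = "little")
    if (rtype == 0L) {  # null shape
      words_read <- words_read + 4L + rec_words
      next
    }
    if (rtype != 5L) stop("non-polygon record in ", shp)
    readBin(con, "numeric", n = 4L, size = 8L, endian = "little")
    n_parts <- readBin(con, "integer", size = 4L, endian = "little")
    n_pts <- readBin(con, "integer", size = 4L, endian = "little")
    starts <- readBin(con, "integer", n = n_parts, size = 4L,
                      endian = "little")
    coords <- readBin(con, "numeric", n = 2L * n_pts, size = 8L,
                      endian = "little")
    pts <- matrix(coords, ncol = 2L, byrow = TRUE)
    ends <- c(starts[-1], n_pts)
    rings <- lapply(seq_len(n_parts), function(k)
      pts[(starts[k] + 1L):ends[k], , drop = FALSE])
    cw <- vapply(rings, function(r) .ring_signed_area(r) < 0, logical(1))
    outer_idx <- which(cw)
    if (length(outer_idx) == 0L) outer_idx <- 1L  # tolerate bad orientation
    polygons[[length(polygons) + 1L]] <-
      list(outer = rings[[outer_idx[1]]],
           holes = rings[setdiff(seq_len(n_parts), outer_idx[1])])
    words_read <- words_read + 4L + rec_words
  }
  dbf <- paste0(base, ".dbf")
  attributes <- if (file.exists(dbf)) .dbf_read(dbf)
                else data.frame(row.names = seq_along(polygons))
  crs <- NA_character_
  prj <- paste0(base, ".prj")
  if (file.exists(prj)) {
    wkt <- paste(readLines(prj, warn = FALSE), collapse = "")
    m <- regmatches(wkt, regexec('AUTHORITY\\["EPSG",\\s*"?([0-9]+)"?\\]',
                                 wkt))[[1]]
    if (length(m) == 2L) crs <- paste0("EPSG:", m[2])
  }
  list(polygons = polygons, attributes = attributes, crs = crs)
}
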