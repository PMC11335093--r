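# Minimal GeoTIFF codec: classic (non-Big) TIFF, uncompressed, strip-based.
# Covers the subset this pipeline writes plus contiguous/separate planar
# layouts and both byte orders on read. No R GIS stack is assumed.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                     `7` = 1L, `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

.tiff_read_values <- function(con, type, count, endian) {
  switch(as.character(type),
    `1` = readBin(con, "integer", n = count, size = 1L, signed = FALSE),
    `2` = {
      raw <- readBin(con, "raw", n = count)
      rawToChar(raw[raw != as.raw(0)])
    },
    `3` = readBin(con, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    `4` = {
      v <- readBin(con, "integer", n = count, size = 4L, endian = endian)
      v <- as.double(v)
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    `6` = readBin(con, "integer", n = count, size = 1L, signed = TRUE),
    `8` = readBin(con, "integer", n = count, size = 2L, signed = TRUE,
                  endian = endian),
    `9` = readBin(con, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(con, "numeric", n = count, size = 4L, endian = endian),
    `12` = readBin(con, "numeric", n = count, size = 8L, endian = endian),
    stop("unsupported TIFF tag type: ", type)
  )
}

.tiff_read_ifd <- function(con, offset, endian) {
  seek(con, offset)
  n_entries <- readBin(con, "integer", size = 2L, signed = FALSE,
                       endian = endian)
  tags <- list()
  entry_base <- offset + 2
  for (i in seq_len(n_entries)) {
    seek(con, entry_base + (i - 1L) * 12L)
    code <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", size = 4L, endian = endian)
    tsize <- .TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(tsize)) next  # RATIONAL etc.: not needed, skip
    nbytes <- as.double(tsize) * count
    if (nbytes > 4) {
      value_offset <- readBin(con, "integer", size = 4L, endian = endian)
      value_offset <- as.double(value_offset)
      if (value_offset < 0) value_offset <- value_offset + 2^32
      seek(con, value_offset)
      vals <- .tiff_read_values(con, type, count, endian)
    } else {
      vals <- .tiff_read_values(con, type, count, endian)
    }
    tags[[as.character(code)]] <- vals
  }
  seek(con, entry_base + n_entries * 12L)
  next_ifd <- readBin(con, "integer", size = 4L, endian = endian)
  list(tags = tags, next_ifd = next_ifd)
}

.tiff_sample_reader <- function(bits, sample_format) {
  # sample_format: 1 unsigned, 2 signed, 3 IEEE float
  key <- paste0(sample_format, ":", bits)
  switch(key,
    "1:8"  = function(con, n, endian) readBin(con, "integer", n, 1L, FALSE),
    "1:16" = function(con, n, endian)
      readBin(con, "integer", n, 2L, FALSE, endian = endian),
    "1:32" = function(con, n, endian) {
      v <- as.double(readBin(con, "integer", n, 4L, endian = endian))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    "2:8"  = function(con, n, endian) readBin(con, "integer", n, 1L, TRUE),
    "2:16" = function(con, n, endian)
      readBin(con, "integer", n, 2L, TRUE, endian = endian),
    "2:32" = function(con, n, endian)
      readBin(con, "integer", n, 4L, endian = endian),
    "3:32" = function(con, n, endian)
      readBin(con, "numeric", n, 4L, endian = endian),
    "3:64" = function(con, n, endian)
      readBin(con, "numeric", n, 8L, endian = endian),
    stop("unsupported TIFF sample type: format ", sample_format, ", ",
         bits, " bits")
  )
}

# Parse a GeoKeyDirectory (tag 34735) into a named list of key -> value.
.tiff_parse_geokeys <- function(gkd) {
  if (is.null(gkd) || length(gkd) < 4) return(list())
  n_keys <- gkd[4]
  keys <- list()
  for (i in seq_len(n_keys)) {
    row <- gkd[(4 + (i - 1) * 4 + 1):(4 + i * 4)]
    if (row[2] == 0) keys[[as.character(row[1])]] <- row[4]
  }
  keys
}

# Read a georeferenced TIFF. Returns list(values = [h, w, bands] double
# array with the raw on-disk values, geotransform, crs, nodata, datatype).
.tiff_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  endian <- if (identical(rawToChar(magic), "II")) "little"
            else if (identical(rawToChar(magic), "MM")) "big"
            else stop("not a TIFF file: ", path)
  forty_two <- readBin(con, "integer", size = 2L, signed = FALSE,
                       endian = endian)
  if (forty_two != 42L) stop("not a classic TIFF file: ", path)
  ifd_offset <- readBin(con, "integer", size = 4L, endian = endian)
  ifd <- .tiff_read_ifd(con, ifd_offset, endian)
  tags <- ifd$tags

  need <- function(code, what) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) stop("TIFF file ", path, " lacks required tag ", what)
    v
  }
  width <- as.integer(need(256, "ImageWidth"))
  height <- as.integer(need(257, "ImageLength"))
  compression <- if (is.null(tags[["259"]])) 1L else as.integer(tags[["259"]])
  if (compression != 1L)
    stop("compressed TIFF not supported (", path, ")")
  if (!is.null(tags[["322"]]))
    stop("tiled TIFF not supported (", path, ")")
  n_bands <- if (is.null(tags[["277"]])) 1L else as.integer(tags[["277"]])
  bits <- if (is.null(tags[["258"]])) 1L else as.integer(tags[["258"]])
  if (length(unique(bits)) != 1L)
    stop("mixed per-band bit depths not supported (", path, ")")
  bits <- bits[1]
  sformat <- if (is.null(tags[["339"]])) 1L else as.integer(tags[["339"]][1])
  planar <- if (is.null(tags[["284"]])) 1L else as.integer(tags[["284"]])
  strip_offsets <- need(273, "StripOffsets")
  strip_counts <- need(279, "StripByteCounts")
  rows_per_strip <- if (is.null(tags[["278"]])) height
                    else as.integer(min(tags[["278"]], height))
  reader <- .tiff_sample_reader(bits, sformat)
  bytes_per <- bits / 8

  read_strip <- function(k) {
    seek(con, strip_offsets[k])
    reader(con, strip_counts[k] / bytes_per, endian)
  }
  n_strips <- length(strip_offsets)
  if (planar == 1L) {
    vec <- unlist(lapply(seq_len(n_strips), read_strip), use.names = FALSE)
    if (length(vec) != as.double(width) * height * n_bands)
      stop("TIFF pixel data truncated (", path, ")")
    arr <- aperm(array(as.double(vec), dim = c(n_bands, width, height)),
                 c(3, 2, 1))
  } else if (planar == 2L) {
    spb <- n_strips / n_bands
    arr <- array(NA_real_, dim = c(height, width, n_bands))
    for (b in seq_len(n_bands)) {
      vec <- unlist(lapply(seq_len(spb) + (b - 1L) * spb, read_strip),
                    use.names = FALSE)
      arr[, , b] <- t(array(as.double(vec), dim = c(width, height)))
    }
  } else stop("unsupported PlanarConfiguration ", planar)

  # georeferencing: ModelPixelScale + ModelTiepoint
  scale <- tags[["33550"]]
  tiepoint <- tags[["33922"]]
  if (is.null(scale) || is.null(tiepoint))
    stop("file ", path, " has no georeferencing ",
         "(ModelPixelScale/ModelTiepoint missing)")
  sx <- scale[1]; sy <- scale[2]
  # tiepoint: raster (i, j, k) <-> model (x, y, z)
  ox <- tiepoint[4] - tiepoint[1] * sx
  oy <- tiepoint[5] + tiepoint[2] * sy
  geotransform <- c(ox, sx, 0, oy, 0, -sy)

  keys <- .tiff_parse_geokeys(tags[["34735"]])
  crs <- NA_character_
  if (!is.null(keys[["3072"]])) crs <- paste0("EPSG:", keys[["3072"]])
  else if (!is.null(keys[["2048"]])) crs <- paste0("EPSG:", keys[["2048"]])

  nodata <- NA_real_
  if (!is.null(tags[["42113"]])) {
    nd <- suppressWarnings(as.numeric(trimws(tags[["42113"]])))
    if (!is.na(nd)) nodata <- nd
  }
  datatype <- switch(paste0(sformat, ":", bits),
                     "1:8" = "UInt8", "1:16" = "UInt16", "1:32" = "UInt32",
                     "2:8" = "Int8", "2:16" = "Int16", "2:32" = "Int32",
                     "3:32" = "Float32", "3:64" = "Float64")
  list(values = arr, geotransform = geotransform, crs = crs,
       nodata = nodata, datatype = datatype)
}

.TIFF_DTYPES <- list(
  UInt8   = list(bits = 8L,  format = 1L),
  UInt16  = list(bits = 16L, format = 1L),
  Int16   = list(bits = 16L, format = 2L),
  Int32   = list(bits = 32L, format = 2L),
  Float32 = list(bits = 32L, format = 3L),
  Float64 = list(bits = 64L, format = 3L)
)

.tiff_write_samples <- function(con, vec, dtype) {
  switch(dtype,
    UInt8 = writeBin(as.integer(vec), con, size = 1L),
    UInt16 = {
      v <- as.integer(vec)  # low two bytes are the unsigned representation
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2L, endian = "little")
    },
    Int16 = writeBin(as.integer(vec), con, size = 2L, endian = "little"),
    Int32 = writeBin(as.integer(vec), con, size = 4L, endian = "little"),
    Float32 = writeBin(as.double(vec), con, size = 4L, endian = "little"),
    Float64 = writeBin(as.double(vec), con, size = 8L, endian = "little"),
    stop("unsupported write datatype ", dtype))
}

# Write a GeoTIFF: little-endian, single strip, contiguous planar layout.
# `values` is an [h, w, bands] array already holding the sentinel (not NA)
# for missing pixels.
.tiff_write <- function(path, values, geotransform, crs = NA_character_,
                        nodata = NA_real_, datatype = "Float64") {
  dt <- .TIFF_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype ", datatype)
  dims <- dim(values)
  h <- dims[1]; w <- dims[2]; s <- if (length(dims) == 3) dims[3] else 1L
  if (length(dims) == 2) dim(values) <- c(h, w, 1L)
  bytes_per <- dt$bits / 8
  strip_bytes <- as.double(h) * w * s * bytes_per
  if (strip_bytes >= 2^31)
    stop("raster too large for single-strip writer")

  # geo keys: model type + raster type (+ EPSG code when known)
  epsg <- NA_integer_
  if (!is.na(crs)) {
    m <- regmatches(crs, regexpr("[0-9]+$", crs))
    if (length(m)) epsg <- as.integer(m)
  }
  geokeys <- list(c(1024L, 0L, 1L, if (!is.na(epsg) &&
                                        epsg >= 4000L && epsg <= 4999L) 2L
                                   else 1L),
                  c(1025L, 0L, 1L, 1L))
  if (!is.na(epsg)) {
    code_key <- if (epsg >= 4000L && epsg <= 4999L) 2048L else 3072L
    geokeys <- c(geokeys, list(c(code_key, 0L, 1L, epsg)))
  }
  gkd <- c(1L, 1L, 0L, length(geokeys), unlist(geokeys))

  sx <- geotransform[2]; sy <- -geotransform[6]
  tiepoint <- c(0, 0, 0, geotransform[1], geotransform[4], 0)

  nodata_str <- if (!is.na(nodata)) {
    s0 <- sprintf("%.17g", nodata)
    charToRaw(paste0(s0, rawToChar(as.raw(0))))
  } else NULL

  # tag table (code, type, values); must stay sorted by code
  tag_list <- list(
    list(256L, 4L, w),
    list(257L, 4L, h),
    list(258L, 3L, rep(dt$bits, s)),
    list(259L, 3L, 1L),
    list(262L, 3L, 1L),
    list(273L, 4L, NA),      # strip offset patched below
    list(277L, 3L, s),
    list(278L, 4L, h),
    list(279L, 4L, strip_bytes)
  )
  tag_list <- c(tag_list, list(list(284L, 3L, 1L)))
  if (s > 1) tag_list <- c(tag_list, list(list(338L, 3L, rep(0L, s - 1L))))
  tag_list <- c(tag_list, list(
    list(339L, 3L, rep(dt$format, s)),
    list(33550L, 12L, c(sx, sy, 0)),
    list(33922L, 12L, tiepoint),
    list(34735L, 3L, gkd)
  ))
  if (!is.null(nodata_str))
    tag_list <- c(tag_list, list(list(42113L, 2L, nodata_str)))

  n_tags <- length(tag_list)
  ifd_offset <- 8L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  overflow_offset <- ifd_offset + ifd_bytes

  tag_bytes <- function(tg) {
    type <- tg[[2]]
    count <- if (type == 2L) length(tg[[3]]) else length(tg[[3]])
    count * .TIFF_TYPE_SIZE[as.character(type)]
  }
  overflow_sizes <- vapply(tag_list, function(tg) {
    nb <- tag_bytes(tg)
    if (nb > 4) as.double(nb + (nb %% 2)) else 0
  }, numeric(1))
  overflow_offsets <- overflow_offset + cumsum(c(0, head(overflow_sizes, -1)))
  data_offset <- overflow_offset + sum(overflow_sizes)
  # patch strip offset
  for (i in seq_along(tag_list))
    if (tag_list[[i]][[1]] == 273L) tag_list[[i]][[3]] <- data_offset

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = "little")
  writeBin(as.integer(n_tags), con, size = 2L, endian = "little")

  write_value_field <- function(tg, i) {
    type <- tg[[2]]; vals <- tg[[3]]
    nb <- tag_bytes(tg)
    count <- if (type == 2L) length(vals) else length(vals)
    writeBin(as.integer(tg[[1]]), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (nb > 4) {
      writeBin(as.integer(overflow_offsets[i]), con, size = 4L,
               endian = "little")
    } else {
      # inline, left-justified, zero-padded to 4 bytes
      before <- seek(con)
      if (type == 3L) {
        v <- as.integer(vals)
        v[v > 32767L] <- v[v > 32767L] - 65536L
        writeBin(v, con, size = 2L, endian = "little")
      } else if (type == 4L) {
        writeBin(as.integer(vals), con, size = 4L, endian = "little")
      } else if (type == 2L) {
        writeBin(vals, con)
      }
      pad <- 4L - (seek(con) - before)
      if (pad > 0) writeBin(raw(pad), con)
    }
  }
  for (i in seq_along(tag_list)) write_value_field(tag_list[[i]], i)
  writeBin(0L, con, size = 4L, endian = "little")  # next IFD

  write_overflow <- function(tg) {
    type <- tg[[2]]; vals <- tg[[3]]
    nb <- tag_bytes(tg)
    if (nb <= 4) return(invisible())
    if (type == 3L) {
      v <- as.integer(vals)
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2L, endian = "little")
    } else if (type == 4L) {
      writeBin(as.integer(vals), con, size = 4L, endian = "little")
    } else if (type == 12L) {
      writeBin(as.double(vals), con, size = 8L, endian = "little")
    } else if (type == 2L) {
      writeBin(vals, con)
    }
    if (nb %% 2) writeBin(raw(1), con)
  }
  for (tg in tag_list) write_overflow(tg)

  stopifnot(seek(con) == data_offset)
  # contiguous layout: band varies fastest, then column, then row
  vec <- aperm(values, c(3, 2, 1))
  .tiff_write_samples(con, as.vector(vec), datatype)
  invisible(path)
}
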