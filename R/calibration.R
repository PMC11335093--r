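#' Calibration panel
#'
#' A reference target of known reflectance used for empirical-line
#' radiometric calibration. Reflectance may be a single value (flat
#' spectrum, applied to every band) or one value per calibrated band.
#'
#' @param polygon panel ROI: two-column vertex matrix or
#'   `list(outer=, holes=)`, in the image CRS.
#' @param reflectance numeric in `[0, 1]`: scalar or named per-band vector
#'   (names from `r, g, b, re, nir`).
#' @param panel_id optional label.
#' @param crs CRS identifier or `NA`.
#' @return object of class `calibration_panel`.
#' @export
calibration_panel <- function(polygon, reflectance, panel_id = NA_character_,
                              crs = NA_character_) {
  if (any(reflectance < 0 | reflectance > 1))
    stop("panel reflectance must lie in [0, 1]")
  roi <- plot_roi(if (is.na(panel_id)) "panel" else panel_id, polygon,
                  crs = crs)
  structure(list(polygon = roi$polygon, reflectance = reflectance,
                 panel_id = panel_id, crs = crs),
            class = "calibration_panel")
}

.panel_reflectance_for <- function(panel, band_name) {
  r <- panel$reflectance
  if (length(r) == 1L && is.null(names(r))) return(unname(r))
  if (!band_name %in% names(r))
    stop("panel has no reflectance for band '", band_name, "'")
  unname(r[[band_name]])
}

#' Fit an empirical-line calibration model
#'
#' For each band bound by `band_map`, regresses the panels' known
#' reflectance on the panel-mean digital number (ordinary least squares):
#' `reflectance = gain * DN + offset`. The mean DN of a panel is taken over
#' pixels whose centers fall inside the panel polygon, with no outlier
#' trimming. With two panels the line interpolates exactly.
#'
#' @param image a [raster_grid()] of digital numbers.
#' @param band_map a [band_map()] for `image`.
#' @param panels list of [calibration_panel()] (at least 2).
#' @return object of class `empirical_line_model`: per band `gain`,
#'   `offset`, `r_squared`, plus `n_panels`.
#' @examples
#' # see fit/recovery tests; gain 0.001 + offset 0.02 reproduces
#' # reflectances 0.12/0.32/0.56 from mean DNs 100/300/540
#' @export
fit_empirical_line <- function(image, band_map, panels) {
  if (length(panels) < 2L)
    stop("empirical-line calibration needs at least 2 panels")
  validate_band_map(band_map, image)
  bands <- names(band_map$bindings)
  model <- list()
  for (nm in bands) {
    b <- band_map$bindings[[nm]]
    dn <- numeric(length(panels))
    rho <- numeric(length(panels))
    for (k in seq_along(panels)) {
      p <- panels[[k]]
      roi <- plot_roi(paste0("panel", k), p$polygon, crs = p$crs)
      clip <- clip_plot(image, roi)
      vals <- clip$values[, , b]
      if (all(is.na(vals)))
        stop("panel ", k, " contains no pixel centers inside the image")
      dn[k] <- mean(vals, na.rm = TRUE)
      rho[k] <- .panel_reflectance_for(p, nm)
    }
    if (max(dn) - min(dn) == 0)
      stop("singular calibration: all panels have identical mean DN in ",
           "band '", nm, "'")
    x <- dn - mean(dn)
    gain <- sum(x * rho) / sum(x * x)
    offset <- mean(rho) - gain * mean(dn)
    fitted <- gain * dn + offset
    ss_res <- sum((rho - fitted)^2)
    ss_tot <- sum((rho - mean(rho))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    # standard error of the slope (used by recovery diagnostics)
    df <- length(panels) - 2L
    se <- if (df > 0) sqrt(ss_res / df / sum(x * x)) else NA_real_
    model[[nm]] <- list(gain = gain, offset = offset, r_squared = r2,
                        gain_se = se)
  }
  structure(list(bands = model, n_panels = length(panels)),
            class = "empirical_line_model")
}

#' @export
print.empirical_line_model <- function(x, ...) {
  cat("<empirical_line_model>", x$n_panels, "panels\n")
  for (nm in names(x$bands)) {
    b <- x$bands[[nm]]
    cat(sprintf("  %-4s gain %.6g offset %.6g R2 %s\n", nm, b$gain,
                b$offset, format(b$r_squared, digits = 6)))
  }
  invisible(x)
}

#' Apply an empirical-line model to an image
#'
#' Per pixel and band: `reflectance = gain * DN + offset`. Nodata pixels
#' stay missing. Values are not clamped unless `clamp = TRUE`, in which
#' case reflectance is clipped to `[0, 1]`; out-of-range pixels are
#' counted and reported via a warning either way.
#'
#' @param image [raster_grid()] of digital numbers.
#' @param model an [fit_empirical_line()] result.
#' @param band_map [band_map()] naming the bands of `image`; every band of
#'   the image must have a model entry.
#' @param clamp clip reflectance to `[0, 1]`? Default `FALSE`.
#' @return reflectance [raster_grid()] (Float64).
#' @export
apply_calibration <- function(image, model, band_map, clamp = FALSE) {
  validate_band_map(band_map, image)
  out <- image$values
  n_out_of_range <- 0L
  covered <- integer(0)
  for (nm in names(band_map$bindings)) {
    entry <- model$bands[[nm]]
    if (is.null(entry)) stop("no calibration entry for band '", nm, "'")
    b <- band_map$bindings[[nm]]
    covered <- c(covered, b)
    v <- entry$gain * image$values[, , b] + entry$offset
    n_out_of_range <- n_out_of_range + sum(v < 0 | v > 1, na.rm = TRUE)
    if (clamp) v <- pmin(pmax(v, 0), 1)
    out[, , b] <- v
  }
  uncovered <- setdiff(seq_len(n_bands(image)), covered)
  if (length(uncovered))
    stop("band(s) without model entry: image band ",
         paste(uncovered, collapse = ", "))
  if (n_out_of_range > 0 && !clamp)
    warning(n_out_of_range, " calibrated pixel(s) outside [0, 1] retained",
            call. = FALSE)
  raster_grid(out, image$geotransform, crs = image$crs,
              nodata = NA_real_, datatype = "Float64")
}

#' Write a per-band calibration report
#'
#' CSV with columns band, gain, offset, r_squared (one row per band),
#' mirroring per-image calibration accuracy reporting.
#'
#' @param model an [fit_empirical_line()] result.
#' @param path destination CSV path.
#' @export
write_calibration_report <- function(model, path) {
  df <- data.frame(
    band = names(model$bands),
    gain = vapply(model$bands, `[[`, numeric(1), "gain"),
    offset = vapply(model$bands, `[[`, numeric(1), "offset"),
    r_squared = vapply(model$bands, `[[`, numeric(1), "r_squared"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load calibration panels from a shapefile plus reflectance CSV
#'
#' The shapefile supplies panel polygons; the CSV supplies reflectances,
#' either a single `reflectance` column (flat spectrum) or one column per
#' canonical band name. Rows are matched to features by order, or by a
#' shared `panel_id` field when both sides have one.
#'
#' @param shp_path panel polygon shapefile.
#' @param csv_path reflectance CSV.
#' @return list of [calibration_panel()].
#' @export
load_panels <- function(shp_path, csv_path) {
  sf <- .read_shapefile(shp_path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  n <- length(sf$polygons)
  if (nrow(tab) != n)
    stop("panel CSV has ", nrow(tab), " rows but shapefile has ", n,
         " features")
  if ("panel_id" %in% names(tab) && "panel_id" %in% names(sf$attributes)) {
    ord <- match(as.character(sf$attributes$panel_id),
                 as.character(tab$panel_id))
    if (anyNA(ord)) stop("panel_id mismatch between shapefile and CSV")
    tab <- tab[ord, , drop = FALSE]
  }
  band_cols <- intersect(c("r", "g", "b", "re", "nir"), names(tab))
  lapply(seq_len(n), function(i) {
    refl <- if (length(band_cols)) {
      stats::setNames(as.numeric(tab[i, band_cols]), band_cols)
    } else if ("reflectance" %in% names(tab)) {
      as.numeric(tab$reflectance[i])
    } else stop("panel CSV needs a 'reflectance' column or per-band columns")
    calibration_panel(sf$polygons[[i]], refl,
                      panel_id = as.character(
                        tab$panel_id[i] %||% paste0("panel", i)),
                      crs = sf$crs)
  })
}
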