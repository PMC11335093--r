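# Per-plot trait extraction: zonal statistics of formula rasters, plant
# height as DSM deviation, empirical-formula biomass, and external-script
# image features.

.ZONAL_STATS <- c("mean", "median", "min", "max", "std", "sum", "count")

#' Zonal statistic of a clipped band
#'
#' Summary over the non-missing pixels of a single-band clip produced by
#' [clip_plot()]. With zero contributing pixels the value is `NA` and a
#' warning is issued.
#'
#' @param clip [raster_grid()] with one band (or a numeric matrix).
#' @param statistic one of `mean, median, min, max, std, sum, count`.
#' @return list with `value` and `n` (contributing pixel count).
#' @export
zonal_stat <- function(clip, statistic = "mean") {
  if (!statistic %in% .ZONAL_STATS)
    stop("unknown statistic '", statistic, "' (use ",
         paste(.ZONAL_STATS, collapse = ", "), ")")
  vals <- if (inherits(clip, "raster_grid")) {
    if (n_bands(clip) != 1L) stop("zonal_stat expects a single band")
    clip$values
  } else clip
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n == 0L) {
    warning("zonal_stat: no contributing pixels", call. = FALSE)
    return(list(value = NA_real_, n = 0L))
  }
  value <- switch(statistic,
    mean = mean(vals), median = stats::median(vals),
    min = min(vals), max = max(vals),
    std = stats::sd(vals), sum = sum(vals), count = as.double(n))
  list(value = value, n = n)
}

.band_slice <- function(raster, b) {
  m <- raster$values[, , b]
  if (!is.matrix(m)) m <- matrix(m, nrow = dim(raster$values)[1])
  m
}

.formula_bindings <- function(clip, band_map, vars) {
  bands <- intersect(vars, names(band_map$bindings))
  out <- list()
  for (nm in bands) out[[nm]] <- .band_slice(clip, band_map$bindings[[nm]])
  out
}

#' Plant height from DSM deviation
#'
#' Mean over the plot's pixels of canopy-surface elevation minus the
#' ground reference: with a scalar ground elevation this equals
#' `mean(DSM within ROI) - ground`; with a bare-soil raster (DTM) sharing
#' the DSM grid, the per-pixel difference is averaged.
#'
#' @param dsm digital surface model [raster_grid()] (single band).
#' @param roi [plot_roi()].
#' @param ground scalar soil elevation or a DTM `raster_grid` on the same
#'   grid as `dsm`. Required: without a soil reference height is undefined.
#' @return list with `value` (height) and `n` (pixel count).
#' @export
extract_height <- function(dsm, roi, ground) {
  if (missing(ground) || is.null(ground))
    stop("no soil reference: supply a scalar ground elevation or a DTM")
  if (inherits(ground, "raster_grid")) {
    if (!identical(dim(ground$values), dim(dsm$values)) ||
        !identical(ground$geotransform, dsm$geotransform))
      stop("DTM must share the DSM grid")
    diff <- raster_grid(dsm$values - ground$values, dsm$geotransform,
                        crs = dsm$crs)
    clip <- clip_plot(diff, roi)
  } else {
    clip <- clip_plot(dsm, roi)
    clip$values <- clip$values - as.double(ground)
  }
  zonal_stat(clip, "mean")
}

#' Biomass from an empirical formula over extracted traits
#'
#' Evaluates a user-supplied empirical formula (for example a fitted
#' height-to-fresh-weight equation exported from the analysis module) on
#' previously extracted scalar traits. A missing or undefined trait input
#' yields `NA` and a log entry rather than an error.
#'
#' @param formula a [parse_formula()] result over trait names.
#' @param traits named list/vector of scalar trait values.
#' @return numeric scalar (possibly `NA`).
#' @examples
#' f <- parse_formula("biomass", "0.5*height")
#' compute_biomass(f, list(height = 1.2))  # 0.6
#' @export
compute_biomass <- function(formula, traits) {
  missing_vars <- setdiff(formula$variables, names(traits))
  if (length(missing_vars)) {
    log_event("biomass '", formula$name, "': undefined trait input(s) ",
              paste(missing_vars, collapse = ", "))
    return(NA_real_)
  }
  vals <- traits[formula$variables]
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1)))) {
    log_event("biomass '", formula$name, "': missing trait value")
    return(NA_real_)
  }
  as.double(evaluate_formula(formula, as.list(traits)))
}

#' External feature-script specification
#'
#' Declares how to invoke a user script that predicts one feature value
#' per plot image, e.g. a deep-learning trait model. The script is run as
#' `interpreter script plot_image_path plot_id [extra_args...]`; the LAST
#' line it prints to standard output must be a single numeric literal.
#'
#' @param interpreter executable path (e.g. a Python interpreter or
#'   `/bin/sh`).
#' @param script script file path.
#' @param extra_args character vector of extra arguments.
#' @param timeout seconds before the call is abandoned (> 0).
#' @return object of class `external_feature_spec`.
#' @export
external_feature_spec <- function(interpreter, script,
                                  extra_args = character(), timeout = 60) {
  if (timeout <= 0) stop("timeout must be positive")
  structure(list(interpreter = interpreter, script = script,
                 extra_args = as.character(extra_args),
                 timeout = as.double(timeout)),
            class = "external_feature_spec")
}

#' Check that an external spec is runnable
#'
#' Called once before a batch starts: a missing interpreter or script is a
#' configuration error, unlike per-plot runtime failures which only yield
#' missing values.
#'
#' @param spec an [external_feature_spec()].
#' @export
validate_external_spec <- function(spec) {
  interp <- Sys.which(spec$interpreter)
  if (!nzchar(interp) && !file.exists(spec$interpreter))
    stop("external interpreter not found: ", spec$interpreter)
  if (!file.exists(spec$script))
    stop("external script not found: ", spec$script)
  invisible(TRUE)
}

#' Run an external feature script for one plot
#'
#' Invokes the script as a subprocess. Nonzero exit status, timeout, or a
#' non-numeric last output line all produce `NA` with a per-plot log entry;
#' the batch is never aborted by a plot-level failure.
#'
#' @param spec an [external_feature_spec()].
#' @param plot_image_path path to the plot's clipped image (GeoTIFF).
#' @param plot_id plot label, passed to the script.
#' @return numeric feature value or `NA`.
#' @export
run_external_feature <- function(spec, plot_image_path, plot_id) {
  args <- c(spec$script, plot_image_path, plot_id, spec$extra_args)
  out <- tryCatch(
    suppressWarnings(system2(spec$interpreter, shQuote(args),
                             stdout = TRUE, stderr = FALSE,
                             timeout = spec$timeout)),
    error = function(e) {
      log_event("external feature for plot ", plot_id, ": ",
                conditionMessage(e))
      NULL
    })
  if (is.null(out)) return(NA_real_)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    log_event("external feature for plot ", plot_id, ": exit status ",
              status)
    return(NA_real_)
  }
  lines <- out[nzchar(trimws(out))]
  if (!length(lines)) {
    log_event("external feature for plot ", plot_id, ": no output")
    return(NA_real_)
  }
  value <- suppressWarnings(as.numeric(trimws(lines[length(lines)])))
  if (is.na(value)) {
    log_event("external feature for plot ", plot_id,
              ": non-numeric output '", lines[length(lines)], "'")
    return(NA_real_)
  }
  value
}

# --- feature specs & strategy -------------------------------------------

#' Extraction strategy and its feature specs
#'
#' An extraction strategy is the ordered recipe of features to compute per
#' plot and date. Four kinds of feature are supported:
#' * `feature_formula()` — a band formula evaluated on a source image and
#'   summarised by a zonal statistic. `eval_mode = "pixel"` (default)
#'   evaluates the formula per pixel and aggregates; `"band_mean"`
#'   aggregates band means first and applies the formula to them (the two
#'   differ for nonlinear formulas).
#' * `feature_height()` — DSM-deviation plant height against a ground
#'   reference.
#' * `feature_biomass()` — an empirical formula over traits computed
#'   earlier in the strategy order.
#' * `feature_external()` — an external script run on the saved plot clip.
#'
#' @param features list of feature specs, names unique; biomass specs may
#'   reference only traits defined earlier in the order.
#' @return object of class `extraction_strategy`.
#' @export
extraction_strategy <- function(features) {
  names_ <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(names_))
    stop("duplicate feature names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  seen <- character()
  for (f in features) {
    if (f$kind == "biomass") {
      undefined <- setdiff(f$formula$variables, seen)
      if (length(undefined))
        stop("biomass feature '", f$name, "' references trait(s) not ",
             "defined earlier: ", paste(undefined, collapse = ", "))
    }
    seen <- c(seen, f$name)
  }
  structure(list(features = features), class = "extraction_strategy")
}

#' @rdname extraction_strategy
#' @param name unique trait name.
#' @param formula [parse_formula()] object (band variables for
#'   `feature_formula`, trait variables for `feature_biomass`).
#' @param source image role: `"rgb"`, `"ms"` or `"dsm"`.
#' @param statistic zonal statistic, default `"mean"`.
#' @param eval_mode `"pixel"` or `"band_mean"`.
#' @export
feature_formula <- function(name, formula, source = "ms",
                            statistic = "mean", eval_mode = "pixel") {
  stopifnot(statistic %in% .ZONAL_STATS, eval_mode %in% c("pixel", "band_mean"))
  list(kind = "formula", name = name, formula = formula, source = source,
       statistic = statistic, eval_mode = eval_mode)
}

#' @rdname extraction_strategy
#' @param ground scalar soil elevation or DTM [raster_grid()].
#' @export
feature_height <- function(name = "height", source = "dsm", ground) {
  if (missing(ground) || is.null(ground))
    stop("no soil reference: height extraction needs 'ground'")
  list(kind = "height", name = name, source = source, ground = ground)
}

#' @rdname extraction_strategy
#' @export
feature_biomass <- function(name, formula) {
  list(kind = "biomass", name = name, formula = formula)
}

#' @rdname extraction_strategy
#' @param spec an [external_feature_spec()].
#' @export
feature_external <- function(name, spec, source = "rgb") {
  list(kind = "external", name = name, spec = spec, source = source)
}

#' Extract all strategy features for one plot
#'
#' Runs each feature spec in order: clip the source image, evaluate the
#' formula, aggregate with the zonal statistic; height from the DSM;
#' biomass over previously computed traits; external scripts on the saved
#' clip (written as `<plot_id>.tif` under `workdir` and retained). A
#' warning is logged when a plot contributes fewer than 5 pixels.
#'
#' @param images named list of [raster_grid()] by role (`rgb`, `ms`,
#'   `dsm`); every role the strategy needs must be present.
#' @param roi [plot_roi()].
#' @param strategy [extraction_strategy()].
#' @param band_maps named list of [band_map()] by role (defaults:
#'   [default_band_map()] for rgb/ms).
#' @param date calendar date (`Date` or string).
#' @param workdir directory for plot clips used by external features.
#' @return a `plot_record`: list with `plot_id`, `date`, `values` (named
#'   numeric, `NA` for failures) and `pixel_counts`.
#' @export
extract_plot <- function(images, roi, strategy, band_maps = list(),
                         date = Sys.Date(), workdir = tempdir()) {
  roles_needed <- unique(unlist(lapply(strategy$features, function(f)
    if (f$kind %in% c("formula", "height", "external")) f$source)))
  missing_roles <- setdiff(roles_needed, names(images))
  if (length(missing_roles)) {
    blocked <- vapply(strategy$features, function(f)
      (f$kind %in% c("formula", "height", "external")) &&
        f$source %in% missing_roles, logical(1))
    stop("missing image role(s) ", paste(missing_roles, collapse = ", "),
         "; blocked features: ",
         paste(vapply(strategy$features[blocked], `[[`, character(1),
                      "name"), collapse = ", "))
  }
  if (is.null(band_maps$rgb) && "rgb" %in% names(images))
    band_maps$rgb <- default_band_map("RGB")
  if (is.null(band_maps$ms) && "ms" %in% names(images))
    band_maps$ms <- default_band_map("MS")

  clips <- list()
  get_clip <- function(role) {
    if (is.null(clips[[role]]))
      clips[[role]] <<- clip_plot(images[[role]], roi)
    clips[[role]]
  }
  values <- numeric(0)
  counts <- integer(0)
  for (f in strategy$features) {
    res <- switch(f$kind,
      formula = {
        clip <- get_clip(f$source)
        bm <- band_maps[[f$source]]
        if (is.null(bm)) stop("no band map for role '", f$source, "'")
        bindings <- .formula_bindings(clip, bm, f$formula$variables)
        unknown <- setdiff(f$formula$variables,
                           c(names(bindings), names(values)))
        if (length(unknown))
          stop("formula '", f$name, "': variable '", unknown[1],
               "' is neither a band of role '", f$source,
               "' nor an earlier trait")
        for (nm in intersect(f$formula$variables, names(values)))
          if (!nm %in% names(bindings)) bindings[[nm]] <- values[[nm]]
        if (f$eval_mode == "pixel") {
          grid <- evaluate_formula(f$formula, bindings)
          zonal_stat(grid, f$statistic)
        } else {
          means <- lapply(bindings, function(m)
            if (is.matrix(m)) mean(m[!is.na(m)]) else m)
          n <- attr(clip, "n_inside")
          list(value = as.double(evaluate_formula(f$formula, means)), n = n)
        }
      },
      height = extract_height(images[[f$source]], roi, f$ground),
      biomass = list(value = compute_biomass(f$formula, as.list(values)),
                     n = NA_integer_),
      external = {
        clip <- get_clip(f$source)
        if (!dir.exists(workdir))
          dir.create(workdir, recursive = TRUE)
        clip_path <- file.path(workdir, paste0(roi$plot_id, ".tif"))
        if (!file.exists(clip_path)) write_raster(clip, clip_path)
        list(value = run_external_feature(f$spec, clip_path, roi$plot_id),
             n = attr(clip, "n_inside"))
      },
      stop("unknown feature kind ", f$kind))
    if (!is.na(res$n %||% NA) && !is.na(res$n) && res$n > 0 && res$n < 5)
      log_event("plot ", roi$plot_id, " feature ", f$name, ": only ",
                res$n, " contributing pixels")
    values[[f$name]] <- res$value
    counts[[f$name]] <- if (is.null(res$n) || is.na(res$n)) NA_integer_
                        else as.integer(res$n)
  }
  structure(list(plot_id = roi$plot_id, date = as.character(date),
                 values = values, pixel_counts = counts),
            class = "plot_record")
}
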