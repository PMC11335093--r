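# Multitemporal batch extraction, date-foldered persistence (CSV/XLSX,
# shapefile with trait attributes, SQLite), and throughput accounting.

#' Batch extraction task
#'
#' @param task_name short task label used in output folder names.
#' @param dates named list: one entry per flight date (name = date string,
#'   coercible by `as.Date`), each a list with any of the image role paths
#'   `rgb`, `ms`, `dsm` and optionally `panels = list(shp =, csv =)` for
#'   per-date empirical-line calibration of the MS image.
#' @param roi_path plot ROI shapefile.
#' @param strategy an [extraction_strategy()].
#' @param id_field ROI attribute holding plot ids (`NULL` = sequential).
#' @param band_maps named list of [band_map()] by role (defaults used when
#'   omitted).
#' @param output_root output directory (created if needed).
#' @param database optional path of an SQLite database to append to.
#' @param write_clips also keep every plot clip of every role (clips used
#'   by external features are always kept).
#' @return object of class `batch_task`.
#' @export
batch_task <- function(task_name, dates, roi_path, strategy,
                       id_field = NULL, band_maps = list(),
                       output_root, database = NULL, write_clips = FALSE) {
  if (!length(dates)) stop("batch task needs at least one date")
  if (is.null(names(dates)) || any(!nzchar(names(dates))))
    stop("'dates' must be a named list keyed by date string")
  structure(list(task_name = task_name, dates = dates, roi_path = roi_path,
                 strategy = strategy, id_field = id_field,
                 band_maps = band_maps, output_root = output_root,
                 database = database, write_clips = write_clips),
            class = "batch_task")
}

.preflight_batch <- function(task) {
  if (!file.exists(task$roi_path))
    stop("ROI shapefile not found: ", task$roi_path)
  for (d in names(task$dates)) {
    entry <- task$dates[[d]]
    for (role in intersect(c("rgb", "ms", "dsm"), names(entry)))
      if (!file.exists(entry[[role]]))
        stop("input for date ", d, " role ", role, " not found: ",
             entry[[role]])
    if (!is.null(entry$panels)) {
      if (!file.exists(entry$panels$shp))
        stop("panel shapefile not found: ", entry$panels$shp)
      if (!file.exists(entry$panels$csv))
        stop("panel CSV not found: ", entry$panels$csv)
    }
  }
  for (f in task$strategy$features)
    if (f$kind == "external") validate_external_spec(f$spec)
  invisible(TRUE)
}

#' Run a batch extraction task
#'
#' For each date: load the rasters, calibrate the MS image when panels are
#' supplied, extract every plot, and write per-date outputs under
#' `output_root/<YYYYMMDD>/<task_name>_<timestamp>/`: a wide CSV table, a
#' copy of the ROI shapefile with one trait attribute column appended per
#' feature, plot clips used by external features, and a calibration report
#' when calibration ran. Per-plot failures become missing values; the
#' batch never aborts on them.
#'
#' @param task a [batch_task()].
#' @return list with `table` (long-format [phenotype_table()] data.frame),
#'   `timing` (a `timing_report`), and `run_dirs` (per-date output paths).
#' @export
run_batch <- function(task) {
  .preflight_batch(task)
  rois <- load_rois(task$roi_path, id_field = task$id_field)
  stamp <- format(Sys.time(), "%Y%m%dT%H%M%S", tz = "UTC")
  long_rows <- list()
  run_dirs <- character(0)
  per_date_minutes <- numeric(0)
  trait_names <- vapply(task$strategy$features, `[[`, character(1), "name")

  for (date_str in names(task$dates)) {
    entry <- task$dates[[date_str]]
    images <- list()
    for (role in intersect(c("rgb", "ms", "dsm"), names(entry)))
      images[[role]] <- load_raster(entry[[role]])
    band_maps <- task$band_maps
    if (is.null(band_maps$ms) && !is.null(images$ms))
      band_maps$ms <- default_band_map("MS")
    if (is.null(band_maps$rgb) && !is.null(images$rgb))
      band_maps$rgb <- default_band_map("RGB")

    date_folder <- format(as.Date(date_str), "%Y%m%d")
    run_dir <- file.path(task$output_root, date_folder,
                         paste0(task$task_name, "_", stamp))
    # idempotent layout: never overwrite an earlier run
    k <- 1L
    while (dir.exists(run_dir)) {
      run_dir <- file.path(task$output_root, date_folder,
                           paste0(task$task_name, "_", stamp, "_", k))
      k <- k + 1L
    }
    dir.create(run_dir, recursive = TRUE)
    run_dirs[date_str] <- run_dir

    model <- NULL
    if (!is.null(entry$panels) && !is.null(images$ms)) {
      panels <- load_panels(entry$panels$shp, entry$panels$csv)
      model <- fit_empirical_line(images$ms, band_maps$ms, panels)
      images$ms <- apply_calibration(images$ms, model, band_maps$ms)
      write_calibration_report(model, file.path(run_dir, "calibration.csv"))
    }

    t0 <- Sys.time()
    records <- vector("list", length(rois))
    for (i in seq_along(rois)) {
      records[[i]] <- tryCatch(
        extract_plot(images, rois[[i]], task$strategy,
                     band_maps = band_maps, date = date_str,
                     workdir = file.path(run_dir, "clips")),
        error = function(e) {
          log_event("plot ", rois[[i]]$plot_id, " date ", date_str,
                    " failed: ", conditionMessage(e))
          structure(list(plot_id = rois[[i]]$plot_id, date = date_str,
                         values = stats::setNames(
                           rep(NA_real_, length(trait_names)), trait_names),
                         pixel_counts = integer(0)),
                    class = "plot_record")
        })
    }
    per_date_minutes[date_str] <-
      as.double(difftime(Sys.time(), t0, units = "mins"))

    if (isTRUE(task$write_clips)) {
      clip_dir <- file.path(run_dir, "clips")
      if (!dir.exists(clip_dir)) dir.create(clip_dir)
      for (role in names(images))
        for (roi in rois) {
          p <- file.path(clip_dir, paste0(roi$plot_id, "_", role, ".tif"))
          if (!file.exists(p))
            write_raster(suppressWarnings(clip_plot(images[[role]], roi)), p)
        }
    }

    values_mat <- vapply(records, function(rec)
      vapply(trait_names, function(tr)
        if (tr %in% names(rec$values)) rec$values[[tr]] else NA_real_,
        numeric(1)),
      numeric(length(trait_names)))
    date_table <- data.frame(
      task = task$task_name, date = date_str,
      plot_id = rep(vapply(records, `[[`, character(1), "plot_id"),
                    each = length(trait_names)),
      trait = rep(trait_names, times = length(records)),
      value = as.vector(values_mat), stringsAsFactors = FALSE)
    long_rows[[date_str]] <- date_table
    utils::write.csv(phenotype_wide(date_table), file.path(
      run_dir, paste0(task$task_name, "_", date_folder, ".csv")),
      row.names = FALSE, na = "")
    append_shapefile_attributes(
      rois, records, file.path(run_dir, paste0(task$task_name, "_",
                                               date_folder, ".shp")))
  }

  table <- phenotype_table(do.call(rbind, long_rows))
  if (!is.null(task$database)) write_database(table, task$database)
  timing <- timing_report(n_plots = length(rois),
                          n_periods = length(task$dates),
                          per_date_minutes = per_date_minutes)
  list(table = table, timing = timing, run_dirs = run_dirs)
}

#' Long-format phenotype table
#'
#' Validates and classes a long-format data.frame with columns `task`,
#' `date`, `plot_id`, `trait`, `value`; `(date, plot_id, trait)` must be
#' unique. `phenotype_wide()` pivots one date (or all, with a date column)
#' to plot x trait.
#'
#' @param df long-format data.frame.
#' @return `df` with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  need <- c("task", "date", "plot_id", "trait", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(df$date, df$plot_id, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (date, plot_id, trait) rows in phenotype table")
  class(df) <- c("phenotype_table", class(df))
  df
}

#' @rdname phenotype_table
#' @export
phenotype_wide <- function(df) {
  traits <- unique(df$trait)
  keys <- unique(df[, c("date", "plot_id")])
  wide <- keys
  for (tr in traits) {
    sub <- df[df$trait == tr, ]
    idx <- match(paste(keys$date, keys$plot_id),
                 paste(sub$date, sub$plot_id))
    wide[[tr]] <- sub$value[idx]
  }
  rownames(wide) <- NULL
  wide
}

#' Write a phenotype table to CSV or XLSX
#'
#' Wide format (plot x trait, one row per date x plot), full float
#' precision, missing values as empty cells. CSV is the canonical output;
#' XLSX delegates to the Python `openpyxl` package (pre-installed
#' alongside) and requires a `python` on the PATH.
#'
#' @param table a [phenotype_table()] (long format).
#' @param path destination path.
#' @param format `"csv"` or `"xlsx"`.
#' @export
write_table <- function(table, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  wide <- phenotype_wide(table)
  if (format == "csv") {
    utils::write.csv(wide, path, row.names = FALSE, na = "")
  } else {
    csv_tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(csv_tmp))
    utils::write.csv(wide, csv_tmp, row.names = FALSE, na = "")
    helper <- system.file("python", "csv_to_xlsx.py", package = "uavpheno")
    status <- system2(Sys.which("python"), shQuote(c(helper, csv_tmp, path)))
    if (status != 0) stop("xlsx export failed (python/openpyxl required)")
  }
  invisible(path)
}

#' Append trait attributes to an ROI shapefile
#'
#' Writes a copy of the ROIs with one attribute column per extracted trait
#' (field names DBF-sanitized to 10 characters, mapping warned about).
#'
#' @param rois list of [plot_roi()].
#' @param records list of plot records (from [extract_plot()]).
#' @param path destination `.shp` path.
#' @export
append_shapefile_attributes <- function(rois, records, path) {
  roi_ids <- vapply(rois, `[[`, character(1), "plot_id")
  rec_ids <- vapply(records, `[[`, character(1), "plot_id")
  orphans <- setdiff(rec_ids, roi_ids)
  if (length(orphans))
    stop("records reference unknown plot id(s): ",
         paste(orphans, collapse = ", "))
  traits <- unique(unlist(lapply(records, function(r) names(r$values))))
  out <- lapply(rois, function(r) {
    rec <- records[[match(r$plot_id, rec_ids)]]
    for (tr in traits)
      r$attributes[[tr]] <- if (!is.na(match(r$plot_id, rec_ids)) &&
                                tr %in% names(rec$values))
        rec$values[[tr]] else NA_real_
    r
  })
  write_rois(out, path)
}

#' Store a phenotype table in an SQLite database
#'
#' Creates (if needed) a long-format table `phenotype` with columns
#' `task, date, plot_id, trait, value` and a uniqueness constraint on
#' `(date, plot_id, trait)`; re-inserting an existing key is an error.
#'
#' @param table a [phenotype_table()].
#' @param target SQLite database file path.
#' @param tbl table name, default `"phenotype"`.
#' @export
write_database <- function(table, target, tbl = "phenotype") {
  con <- DBI::dbConnect(RSQLite::SQLite(), target)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, sprintf(
    "CREATE TABLE IF NOT EXISTS %s (
       task TEXT, date TEXT, plot_id TEXT, trait TEXT, value REAL,
       UNIQUE(date, plot_id, trait))", tbl))
  if (nrow(table) > 0) {
    df <- as.data.frame(table)[, c("task", "date", "plot_id", "trait",
                                   "value")]
    DBI::dbWithTransaction(con, {
      DBI::dbExecute(con, sprintf(
        "INSERT INTO %s (task, date, plot_id, trait, value)
         VALUES (:task, :date, :plot_id, :trait, :value)", tbl),
        params = as.list(df))
    })
  }
  invisible(target)
}

# --- throughput accounting ----------------------------------------------

#' Timing report for a batch run
#'
#' Efficiency is the number of plot-date combinations processed per minute
#' of extraction wall time: `n_plots * n_periods / total_minutes`. Timing
#' covers the extraction loop only (input mosaic I/O excluded).
#'
#' @param n_plots,n_periods counts.
#' @param per_date_minutes named numeric of per-date wall durations.
#' @return object of class `timing_report`.
#' @export
timing_report <- function(n_plots, n_periods, per_date_minutes) {
  total <- sum(per_date_minutes)
  structure(list(n_plots = n_plots, n_periods = n_periods,
                 per_date_minutes = per_date_minutes,
                 total_minutes = total,
                 efficiency = if (total > 0)
                   n_plots * n_periods / total else NA_real_),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf(
    "<timing_report> %d plots x %d periods in %.2f min (%.2f plots/min)\n",
    x$n_plots, x$n_periods, x$total_minutes, x$efficiency))
  invisible(x)
}

#' Processing-efficiency arithmetic
#'
#' Given replicate working times of one benchmark configuration, reports
#' the mean working time and the efficiency in plots per minute:
#' `n_plots * n_periods / mean_minutes`, where the mean is taken at full
#' precision (rounded values are provided alongside for display).
#'
#' @param n_plots number of plots per image.
#' @param n_periods number of image dates processed.
#' @param run_minutes numeric vector of replicate wall times in minutes.
#' @return list: `mean_minutes`, `efficiency` (full precision) and
#'   `mean_minutes_2dp`, `efficiency_2dp` (rounded to 2 decimals).
#' @examples
#' compute_efficiency(484, 25, c(7.35, 7.9, 6.98))$efficiency_2dp  # 1632.93
#' @export
compute_efficiency <- function(n_plots, n_periods, run_minutes) {
  if (!length(run_minutes)) stop("empty duration list")
  if (any(run_minutes <= 0)) stop("durations must be positive")
  m <- mean(run_minutes)
  eff <- n_plots * n_periods / m
  list(mean_minutes = m, efficiency = eff,
       mean_minutes_2dp = round(m, 2), efficiency_2dp = round(eff, 2))
}

#' Benchmark configurations of the software performance test
#'
#' The 16 benchmark configurations (plots, periods, database on/off,
#' external deep-learning feature on/off) with their three replicate
#' working times in minutes. These replicate times are the inputs from
#' which mean working time and efficiency are recomputed with
#' [compute_efficiency()].
#'
#' @return data.frame with columns `test`, `plots`, `periods`, `db`, `dl`,
#'   `r1`, `r2`, `r3`.
#' @export
timing_trials <- function() {
  data.frame(
    test = paste0("T", 1:16),
    plots = c(484, 484, 484, 484, 600, 600, 600, 600,
              800, 800, 800, 800, 1000, 1000, 1000, 1000),
    periods = c(10, 15, 25, 40, 10, 15, 25, 40,
                10, 15, 25, 40, 10, 15, 25, 40),
    db = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
           FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    dl = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
           TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    r1 = c(8.3, 12.31, 7.35, 12.51, 4.01, 6.13, 25.94, 41.94,
           16.02, 25.08, 17.66, 26.46, 6.7, 10.65, 43.87, 75.96),
    r2 = c(8.19, 12.68, 7.9, 12.37, 4.21, 6.05, 25.76, 42.03,
           15.45, 24.86, 17.09, 26.85, 5.98, 10.8, 43.2, 74.5),
    r3 = c(8.25, 12.5, 6.98, 12.19, 4.07, 6.04, 25.81, 42.31,
           15.1, 24.3, 17.45, 26.19, 6.65, 10.21, 44.9, 72.1),
    stringsAsFactors = FALSE)
}
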