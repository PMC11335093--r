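# batch_store: orchestration, persistence, efficiency arithmetic.

make_batch_fixture <- function(dir, n_rows = 2, n_cols = 5, dates = 2,
                               stub_behavior = "constant") {
  field <- make_small_field(file.path(dir, "field"), n_rows = n_rows,
                            n_cols = n_cols)
  stub <- generate_stub_script(file.path(dir, "stub.sh"), stub_behavior,
                               value = 2.5)
  strat <- extraction_strategy(list(
    feature_formula("NDVI", get_preset("NDVI", "MS"), source = "ms"),
    feature_height("height", ground = field$truth$ground_elev),
    feature_external("stub", external_feature_spec(stub$interpreter,
                                                   stub$script))))
  date_names <- format(as.Date("2024-07-01") + seq_len(dates) - 1)
  date_list <- stats::setNames(lapply(date_names, function(d) list(
    ms = field$paths$ms, rgb = field$paths$rgb, dsm = field$paths$dsm,
    panels = list(shp = field$paths$panels_shp,
                  csv = field$paths$panels_csv))), date_names)
  task <- batch_task("demo", date_list, field$paths$rois, strat,
                     id_field = "plot_id",
                     output_root = file.path(dir, "out"),
                     database = file.path(dir, "pheno.sqlite"))
  list(field = field, task = task)
}

test_that("run_batch yields a complete long table and date folders", {
  dir <- tempfile()
  dir.create(dir)
  fx <- make_batch_fixture(dir, n_rows = 2, n_cols = 5, dates = 2)
  res <- run_batch(fx$task)
  # 10 plots x 2 dates x 3 traits
  expect_identical(nrow(res$table), 60L)
  expect_s3_class(res$table, "phenotype_table")
  expect_false(anyNA(res$table$value))
  expect_length(res$run_dirs, 2)
  expect_true(all(dir.exists(res$run_dirs)))
  expect_match(res$run_dirs[1], "20240701/demo_")
  # per-date outputs: CSV, shapefile, calibration report, clips
  d1 <- res$run_dirs[1]
  expect_true(file.exists(file.path(d1, "demo_20240701.csv")))
  expect_true(file.exists(file.path(d1, "demo_20240701.shp")))
  expect_true(file.exists(file.path(d1, "calibration.csv")))
  expect_true(file.exists(file.path(d1, "clips", "P0001.tif")))
  # calibrated NDVI matches truth through the whole batch
  ndvi <- res$table[res$table$trait == "NDVI" &
                      res$table$date == "2024-07-01", ]
  expect_equal(ndvi$value[match(fx$field$truth$plots$plot_id,
                                ndvi$plot_id)],
               fx$field$truth$plots$NDVI, tolerance = 1e-9)
  # timing accounts plots x periods / minutes
  expect_identical(res$timing$n_plots, 10L)
  expect_identical(res$timing$n_periods, 2L)
  expect_equal(res$timing$efficiency,
               20 / res$timing$total_minutes)
  # shapefile got the trait columns
  back <- load_rois(file.path(d1, "demo_20240701.shp"),
                    id_field = "plot_id")
  expect_true(all(c("NDVI", "height", "stub") %in%
                    names(back[[1]]$attributes)))
  # rerunning never overwrites: a new run dir appears (database dropped —
  # re-inserting the same keys is a constraint violation by design)
  fx$task$database <- NULL
  res2 <- run_batch(fx$task)
  expect_false(any(res2$run_dirs %in% res$run_dirs))
})

test_that("a failing external script leaves only its cells missing", {
  dir <- tempfile()
  dir.create(dir)
  fx <- make_batch_fixture(dir, n_rows = 1, n_cols = 4, dates = 1,
                           stub_behavior = "fail")
  fx$task$database <- NULL
  res <- run_batch(fx$task)
  expect_identical(nrow(res$table), 12L)  # conservation: rows not dropped
  stub_rows <- res$table[res$table$trait == "stub", ]
  expect_true(all(is.na(stub_rows$value)))
  other <- res$table[res$table$trait != "stub", ]
  expect_false(anyNA(other$value))
})

test_that("pre-flight errors fire before any extraction", {
  dir <- tempfile()
  dir.create(dir)
  fx <- make_batch_fixture(dir, n_rows = 1, n_cols = 2, dates = 1)
  bad <- fx$task
  bad$dates[[1]]$ms <- "/no/such/ms.tif"
  expect_error(run_batch(bad), "not found")
  expect_false(dir.exists(file.path(dir, "out")))
})

test_that("write_table round-trips CSV and handles empty/missing", {
  long <- phenotype_table(data.frame(
    task = "t", date = rep(c("2024-07-01", "2024-07-02"), each = 4),
    plot_id = rep(c("P1", "P2"), 4),
    trait = rep(rep(c("NDVI", "height"), each = 2), 2),
    value = c(0.51234567891234, 0.6, 1.1, NA, 0.7, 0.8, 1.3, 1.4),
    stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".csv")
  write_table(long, path, format = "csv")
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 4L)  # 2 dates x 2 plots
  expect_identical(names(back), c("date", "plot_id", "NDVI", "height"))
  # full float precision round-trip
  expect_equal(back$NDVI[1], 0.51234567891234, tolerance = 1e-15)
  # missing as empty cell, not zero
  expect_true(is.na(back$height[2]))
  raw <- readLines(path)
  expect_match(raw[3], ",$")
  # empty table: header-only file
  empty <- phenotype_table(long[0, ])
  p2 <- tempfile(fileext = ".csv")
  write_table(empty, p2)
  expect_identical(length(readLines(p2)), 1L)
})

test_that("xlsx export round-trips through an independent reader", {
  skip_if_not_installed("readxl")
  long <- phenotype_table(data.frame(
    task = "t", date = "2024-07-01", plot_id = c("P1", "P2"),
    trait = "NDVI", value = c(0.25, NA), stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".xlsx")
  write_table(long, path, format = "xlsx")
  back <- as.data.frame(readxl::read_excel(path))
  expect_identical(nrow(back), 2L)
  expect_equal(back$NDVI[1], 0.25)
  expect_true(is.na(back$NDVI[2]))
})

test_that("append_shapefile_attributes adds one field per trait", {
  rois <- replicate_roi(square_roi("T", 0, 20, 2), 5, 2, 3, 3)
  records <- lapply(rois, function(r)
    list(plot_id = r$plot_id,
         values = c(NDVI = 0.5, height = 1.2)))
  path <- file.path(tempfile(), "app.shp")
  dir.create(dirname(path))
  append_shapefile_attributes(rois, records, path)
  back <- load_rois(path, id_field = "plot_id")
  expect_length(back, 10)
  expect_true(all(c("NDVI", "height") %in% names(back[[1]]$attributes)))
  expect_equal(back[[3]]$attributes$height, 1.2)
  # orphan record
  bad <- c(records, list(list(plot_id = "GHOST", values = c(NDVI = 1))))
  expect_error(append_shapefile_attributes(rois, bad, path),
               "unknown plot id.*GHOST")
  # DBF truncation of long trait names warns
  rec2 <- lapply(rois, function(r)
    list(plot_id = r$plot_id,
         values = c(normalized_difference_vi = 0.1)))
  expect_warning(append_shapefile_attributes(
    rois, rec2, file.path(dirname(path), "app2.shp")), "adjusted")
})

test_that("write_database stores long rows with key uniqueness", {
  long <- phenotype_table(data.frame(
    task = "t", date = rep("2024-07-01", 6),
    plot_id = rep(c("P1", "P2", "P3"), each = 2),
    trait = rep(c("NDVI", "height"), 3),
    value = as.double(1:6), stringsAsFactors = FALSE))
  db <- tempfile(fileext = ".sqlite")
  write_database(long, db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  expect_identical(
    DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM phenotype")$n, 6L)
  got <- DBI::dbGetQuery(con,
    "SELECT value FROM phenotype WHERE plot_id = 'P2' AND trait = 'NDVI'")
  expect_equal(got$value, 3)
  # duplicate keys violate the constraint
  expect_error(write_database(long, db), "UNIQUE|unique")
  # empty table: created, zero rows
  db2 <- tempfile(fileext = ".sqlite")
  write_database(phenotype_table(long[0, ]), db2)
  con2 <- DBI::dbConnect(RSQLite::SQLite(), db2)
  on.exit(DBI::dbDisconnect(con2), add = TRUE)
  expect_identical(
    DBI::dbGetQuery(con2, "SELECT COUNT(*) n FROM phenotype")$n, 0L)
})

test_that("phenotype_table enforces key uniqueness", {
  df <- data.frame(task = "t", date = "d", plot_id = "P1", trait = "x",
                   value = 1:2 * 1.0)
  expect_error(phenotype_table(df), "duplicate")
  expect_error(phenotype_table(df[, -5]), "lacks column")
})

test_that("compute_efficiency reproduces all 16 published benchmark rows", {
  trials <- timing_trials()
  printed <- printed_performance()
  for (i in seq_len(nrow(trials))) {
    eff <- compute_efficiency(trials$plots[i], trials$periods[i],
                              unlist(trials[i, c("r1", "r2", "r3")]))
    expect_identical(eff$mean_minutes_2dp, printed$mean_2dp[i],
                     label = trials$test[i])
    expect_identical(eff$efficiency_2dp, printed$eff_2dp[i],
                     label = trials$test[i])
  }
  # unit case and contracts
  expect_equal(compute_efficiency(1, 1, 1.0),
               list(mean_minutes = 1, efficiency = 1,
                    mean_minutes_2dp = 1, efficiency_2dp = 1))
  expect_error(compute_efficiency(1, 1, numeric()), "empty")
  expect_error(compute_efficiency(1, 1, c(1, -2)), "positive")
})
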