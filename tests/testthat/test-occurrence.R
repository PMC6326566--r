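write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("species_id,sex,date,lat,lon,altitude,biotope,count,colours", lines),
             path)
  path
}

test_that("valid rows load; invalid rows are rejected with row and reason", {
  path <- write_csv_fixture(c(
    "sp1,male,2010-06-01,50.0,15.0,300,pond,1,red|blue",
    "sp2,,2011-07-12,49.5,14.2,,,2-5,",
    "sp3,female,2012-08-01,48.9,16.1,450,river,3,"
  ))
  recs <- read_records(path)
  expect_equal(nrow(recs), 3)
  expect_equal(nrow(rejections(recs)), 0)
  expect_equal(recs$sex[2], "unknown") # empty sex defaults to unknown
  expect_equal(recs$colours[[1]], c("red", "blue"))
  expect_true(is.na(recs$altitude[2]))

  path <- write_csv_fixture(c(
    "sp1,male,2010-06-01,95,15.0,300,pond,1,",        # latitude out of range
    "sp1,male,2010-06-01,50.0,15.0,300,pond,1,red|blue|green|black", # 4 colours
    "sp1,male,2010-06-01,50.0,15.0,300,pond,1,"
  ))
  recs <- read_records(path)
  expect_equal(nrow(recs), 1)
  rej <- rejections(recs)
  expect_equal(rej$row, c(1L, 2L))
  expect_match(rej$reason[1], "latitude out of range")
  expect_match(rej$reason[2], "more than 3 colours")
})

test_that("other per-row defects are reported by reason", {
  path <- write_csv_fixture(c(
    "sp1,male,junk,50.0,15.0,,,,",
    "sp1,male,2010-06-01,50.0,200,,,,",
    "sp1,neither,2010-06-01,50.0,15.0,,,,",
    "sp1,male,2010-06-01,50.0,15.0,,moonbase,,",
    "sp1,male,2010-06-01,50.0,15.0,,,0,",
    "sp1,male,2010-06-01,50.0,15.0,,,,mauve"
  ))
  recs <- read_records(path)
  expect_equal(nrow(recs), 0)
  expect_equal(
    rejections(recs)$reason,
    c("invalid or missing date", "longitude out of range", "invalid sex",
      "unknown biotope", "invalid count", "unknown colour")
  )
})

test_that("a missing mandatory column is an I/O failure", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,sex,date,lat,lon", "sp1,male,2010-06-01,50,15"), path)
  expect_error(read_records(path), "colum", class = "odofuzz_io_error")
})

test_that("records CSV write/read round trip preserves content", {
  recs <- make_records(c("a", "b"), colours = list(c("red"), character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(recs, path)
  back <- read_records(path, colour_vocabulary = odo_colours())
  expect_equal(back$species_id, recs$species_id)
  expect_equal(back$date, recs$date)
  expect_equal(back$colours, recs$colours)
})

test_that("grid cells follow the half-open floor convention", {
  grid <- grid_config(dlat = 0.1, dlon = 10 / 60, lat0 = 48, lon0 = 12)
  # hand computation: floor(2.05/0.1) = 20, floor(5.0/(1/6)) = 30
  expect_equal(gps_to_grid_cell(50.05, 17.00, grid),
               tibble::tibble(row = 20L, col = 30L))
  # two nearby points share a cell
  expect_equal(gps_to_grid_cell(50.051, 17.001, grid),
               gps_to_grid_cell(50.059, 17.009, grid))
  # a point exactly on the northern/eastern boundary belongs to the
  # higher-indexed cell
  expect_equal(gps_to_grid_cell(48.1, 12 + 10 / 60, grid),
               tibble::tibble(row = 1L, col = 1L))
})

test_that("cells tile a 1x1 degree box with no gaps or overlaps", {
  grid <- grid_config(dlat = 0.1, dlon = 10 / 60, lat0 = 50, lon0 = 14)
  # exhaustive 0.001-degree lattice; integer arithmetic is the oracle
  milli <- 0:999
  lat_off <- rep(milli, each = 1000)
  lon_off <- rep(milli, times = 1000)
  cells <- gps_to_grid_cell(50 + lat_off / 1000, 14 + lon_off / 1000, grid)
  expect_false(anyNA(cells$row))
  expect_false(anyNA(cells$col))
  expect_equal(cells$row, as.integer(lat_off %/% 100))
  # longitude cells are 1/6 degree = 1000/6 millidegrees wide; the oracle
  # floors exact thousandths against the rational width: floor(6m/1000)
  expect_equal(cells$col, as.integer((lon_off * 6) %/% 1000))
  expect_equal(sort(unique(cells$row)), 0:9)
  expect_equal(sort(unique(cells$col)), 0:5)
})

test_that("filter_from_year keeps the cutoff year and later, in order", {
  recs <- make_records("sp1",
                       date = as.Date(c("1999-06-01", "2002-01-01", "2010-08-15")))
  kept <- filter_from_year(recs, 2002)
  expect_equal(format(kept$date, "%Y"), c("2002", "2010"))
  expect_equal(filter_from_year(recs, 1999), recs)
  expect_equal(nrow(filter_from_year(recs[0, ], 2002)), 0)
})

test_that("stratified_split is per-species, seeded and partitioning", {
  recs <- make_records(c(rep("common", 100), rep("rare", 1)),
                       lat = seq(48, 51, length.out = 101))
  parts <- stratified_split(recs, 0.2, seed = 11)
  expect_equal(sum(parts$train$species_id == "common"), 80)
  expect_equal(sum(parts$test$species_id == "common"), 20)
  # a species whose share rounds to zero keeps its record in training
  expect_equal(sum(parts$train$species_id == "rare"), 1)
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(recs))

  again <- stratified_split(recs, 0.2, seed = 11)
  expect_identical(parts$test, again$test)
  other <- stratified_split(recs, 0.2, seed = 12)
  expect_false(identical(parts$test, other$test))
})

test_that("split proportions hold within one record per species", {
  withr::with_seed(5, {
    recs <- make_records(sample(sprintf("sp%02d", 1:12), 500, replace = TRUE))
  })
  parts <- stratified_split(recs, 0.3, seed = 6)
  for (sp in unique(recs$species_id)) {
    n <- sum(recs$species_id == sp)
    n_test <- sum(parts$test$species_id == sp)
    expect_lte(abs(n_test - n * 0.3), 1)
  }
})
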