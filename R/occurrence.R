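#' Grid configuration for presence lookup
#'
#' Observations are binned into a latitude/longitude graticule. The
#' default is the Central European faunistic mapping (KFME) cell size of
#' 6 arc-minutes latitude by 10 arc-minutes longitude, which at Czech
#' latitudes measures roughly 11.1 x 11.9 km. Cells are half-open
#' `[low, high)` in both axes, so a point exactly on a cell's
#' northern/eastern boundary belongs to the higher-indexed cell.
#'
#' @param dlat,dlon Cell height/width in decimal degrees.
#' @param lat0,lon0 Grid origin (degrees); cell (0, 0) has its south-west
#'   corner here.
#' @return A `odo_grid` list.
#' @export
grid_config <- function(dlat = 6 / 60, dlon = 10 / 60, lat0 = 0, lon0 = 0) {
  stopifnot(dlat > 0, dlon > 0)
  structure(list(dlat = dlat, dlon = dlon, lat0 = lat0, lon0 = lon0),
            class = "odo_grid")
}

#' Map GPS coordinates to grid cells
#'
#' Vectorised over `lat`/`lon`. Index arithmetic is guarded against
#' floating-point representation of exact boundaries (a point within
#' 1e-9 cell widths below a boundary is assigned to the boundary's cell),
#' so the half-open convention holds for representable coordinates.
#'
#' @param lat,lon Numeric vectors of WGS84 decimal degrees.
#' @param grid A [grid_config()].
#' @return A tibble with integer columns `row` (latitude index) and
#'   `col` (longitude index).
#' @examples
#' gps_to_grid_cell(50.05, 17.00, grid_config(0.1, 10 / 60, 48, 12))
#' @export
gps_to_grid_cell <- function(lat, lon, grid = grid_config()) {
  tibble::tibble(
    row = grid_index(lat, grid$lat0, grid$dlat),
    col = grid_index(lon, grid$lon0, grid$dlon)
  )
}

grid_index <- function(x, x0, dx) {
  as.integer(floor((x - x0) / dx + 1e-9))
}

# internal: "species|row|col" keys for fast presence membership tests
presence_keys <- function(species_id, lat, lon, grid) {
  cell <- gps_to_grid_cell(lat, lon, grid)
  paste(species_id, cell$row, cell$col, sep = "|")
}

#' Read occurrence records from CSV
#'
#' Expects a UTF-8 CSV with header
#' `species_id,sex,date,lat,lon,altitude,biotope,count,colours`;
#' `colours` is a `|`-separated list of at most three colour codes.
#' `sex`, `altitude`, `biotope`, `count` and `colours` may be empty.
#' Every row either becomes a valid record or is dropped and reported
#' with its row number and reason; retrieve the report with
#' [rejections()].
#'
#' @param path CSV file path.
#' @param colour_vocabulary,biotope_vocabulary Allowed codes.
#' @return A tibble of records (class `odo_records`) with a `rejections`
#'   attribute; `colours` is a list-column of character vectors.
#' @export
read_records <- function(path,
                         colour_vocabulary = odo_colours(),
                         biotope_vocabulary = odo_biotopes()) {
  if (!file.exists(path)) {
    odo_abort(sprintf("records file not found: %s", path), "odofuzz_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("species_id", "sex", "date", "lat", "lon", "altitude",
                "biotope", "count", "colours")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    odo_abort(
      sprintf("records file lacks mandatory column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "odofuzz_io_error"
    )
  }
  validate_records(raw, colour_vocabulary, biotope_vocabulary)
}

#' @rdname read_records
#' @param x An `odo_records` tibble.
#' @return `rejections()`: a tibble with columns `row` and `reason`.
#' @export
rejections <- function(x) {
  rej <- attr(x, "rejections")
  if (is.null(rej)) rej <- tibble::tibble(row = integer(), reason = character())
  rej
}

# row-wise validation of a character data frame into typed records
validate_records <- function(raw, colour_vocabulary, biotope_vocabulary) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  altitude <- suppressWarnings(as.numeric(raw$altitude))
  sex <- dplyr::coalesce(raw$sex, "unknown")
  colours <- purrr::map(raw$colours, function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })

  flag(is.na(raw$species_id) | raw$species_id == "", "missing species_id")
  flag(!sex %in% c(odo_sexes(), "unknown"), "invalid sex")
  flag(is.na(date), "invalid or missing date")
  flag(is.na(lat) | lat < -90 | lat > 90, "latitude out of range")
  flag(is.na(lon) | lon < -180 | lon > 180, "longitude out of range")
  flag(!is.na(raw$altitude) & is.na(altitude), "non-numeric altitude")
  flag(!is.na(raw$biotope) & !raw$biotope %in% biotope_vocabulary, "unknown biotope")
  flag(purrr::map_int(colours, length) > 3, "more than 3 colours")
  flag(!purrr::map_lgl(colours, ~ all(.x %in% colour_vocabulary)), "unknown colour")
  count_ok <- is.na(raw$count) |
    raw$count %in% odo_abundance_classes() |
    grepl("^[1-9][0-9]*$", raw$count)
  flag(!count_ok, "invalid count")

  keep <- is.na(reason)
  out <- tibble::tibble(
    species_id = raw$species_id[keep],
    sex = sex[keep],
    date = date[keep],
    lat = lat[keep],
    lon = lon[keep],
    altitude = altitude[keep],
    biotope = raw$biotope[keep],
    count = raw$count[keep],
    colours = colours[keep]
  )
  attr(out, "rejections") <- tibble::tibble(
    row = which(!keep),
    reason = reason[!keep]
  )
  class(out) <- c("odo_records", class(out))
  out
}

#' Keep records from a given year onwards
#'
#' The published model used records from 2002 and later; the cutoff is a
#' parameter here.
#'
#' @param records A records tibble with a `date` column.
#' @param year First calendar year to keep.
#' @return The filtered tibble, order preserved.
#' @export
filter_from_year <- function(records, year) {
  records[record_year(records$date) >= year, , drop = FALSE]
}

record_year <- function(date) as.integer(format(date, "%Y"))

record_day_of_year <- function(date) as.POSIXlt(date)$yday + 1L

#' Stratified train/test split by species
#'
#' Within each species, `round(n * test_fraction)` records are sampled
#' without replacement into the test set (half-to-even rounding; a
#' species whose share rounds to 0 keeps all records in training). Train
#' and test partition the input and the split is deterministic given the
#' seed.
#'
#' @param records A records tibble with a `species_id` column.
#' @param test_fraction Fraction in (0, 1); default 0.2.
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(records, test_fraction = 0.2, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  withr::with_seed(seed, {
    test_idx <- integer()
    for (sp in sort(unique(records$species_id))) {
      idx <- which(records$species_id == sp)
      n_test <- round(length(idx) * test_fraction)
      if (n_test > 0) {
        test_idx <- c(test_idx, idx[sample.int(length(idx), n_test)])
      }
    }
    test_idx <- sort(test_idx)
  })
  list(
    train = records[setdiff(seq_len(nrow(records)), test_idx), , drop = FALSE],
    test = records[test_idx, , drop = FALSE]
  )
}
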