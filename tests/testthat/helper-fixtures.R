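# Shared fixtures: a hand-written 3-species knowledge base, record builders,
# and the explicit-loop brute-force oracle for the colour coefficient.

toy_kb <- function() {
  knowledge_base(list(
    species_knowledge(
      "aeshna_demo", "anisoptera",
      seasonality = trapezoid(120, 150, 220, 250),
      altitude = trapezoid(200, 300, 800, 1000),
      colours_additive = list(male = c(blue = 1, brown = 0.5),
                              female = c(brown = 1)),
      colours_exclusion = list(male = c(red = 0), female = c())
    ),
    species_knowledge(
      "libellula_demo", "anisoptera",
      seasonality = trapezoid(100, 130, 200, 230),
      altitude = trapezoid(100, 150, 500, 700),
      colours_additive = list(male = c(red = 1, orange = 0.5),
                              female = c(yellow = 1)),
      colours_exclusion = list(male = c(green = 0), female = c())
    ),
    species_knowledge(
      "coenagrion_demo", "zygoptera",
      seasonality = trapezoid(130, 160, 210, 240),
      altitude = trapezoid(150, 200, 600, 800),
      colours_additive = list(male = c(blue = 1, black = 0.5),
                              female = c(green = 1)),
      colours_exclusion = list(male = c(), female = c(red = 0, orange = 0))
    )
  ))
}

# a records tibble from parallel vectors, with sensible defaults
make_records <- function(species_id,
                         sex = "male",
                         date = as.Date("2010-07-01"),
                         lat = 50.0, lon = 15.0,
                         altitude = 400,
                         biotope = "pond",
                         count = "1",
                         colours = NULL) {
  n <- max(length(species_id), length(sex), length(date), length(lat),
           length(lon), length(altitude), length(biotope))
  if (length(species_id) == 0) n <- 0
  if (is.null(colours)) colours <- rep(list(character()), n)
  tibble::tibble(
    species_id = rep_len(species_id, n),
    sex = rep_len(sex, n),
    date = rep_len(as.Date(date), n),
    lat = rep_len(lat, n),
    lon = rep_len(lon, n),
    altitude = rep_len(altitude, n),
    biotope = rep_len(biotope, n),
    count = rep_len(count, n),
    colours = rep_len(colours, n)
  )
}

toy_model <- function(records = NULL) {
  kb <- toy_kb()
  if (is.null(records)) {
    records <- make_records(
      species_id = c(rep("aeshna_demo", 4), rep("libellula_demo", 8),
                     rep("coenagrion_demo", 2)),
      biotope = c(rep("pond", 10), rep("river", 4))
    )
  }
  fit_model(kb, records)
}

# independent oracle: the colour composition written as explicit loops over
# the vocabulary, never touching the package's vectorised path
brute_colour_coefficient <- function(selected_bin, S, A_col, E_col,
                                     weight = 0.7, offset = 0.3) {
  nc <- length(selected_bin)
  if (sum(selected_bin) == 0) {
    return(1)
  }
  v <- numeric(nc)
  for (cp in seq_len(nc)) {
    for (cc in seq_len(nc)) {
      if (selected_bin[cc] == 1) {
        v[cp] <- max(v[cp], min(selected_bin[cc], S[cc, cp]))
      }
    }
  }
  w <- 0
  for (cp in seq_len(nc)) {
    w <- max(w, min(v[cp], A_col[cp]))
  }
  x <- 1
  for (cc in seq_len(nc)) {
    if (selected_bin[cc] == 1) {
      x <- min(x, E_col[cc])
    }
  }
  min(weight * w + offset, x)
}

# random symmetric unit-diagonal similarity matrix over the colour vocabulary
random_similarity <- function() {
  nc <- length(odo_colours())
  S <- matrix(stats::runif(nc * nc), nc, nc)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(odo_colours(), odo_colours())
  S
}

random_binary_selection <- function(max_ones = 3) {
  nc <- length(odo_colours())
  k <- sample(0:max_ones, 1)
  sel <- rep(0, nc)
  if (k > 0) sel[sample.int(nc, k)] <- 1
  sel
}
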