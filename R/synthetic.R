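#' Configuration of the synthetic-data generator
#'
#' The generator emulates the structure of a national odonate
#' occurrence database and its expert knowledge base so the whole
#' pipeline is testable without any real data: a power-law species
#' abundance distribution, seasonal flight windows between early March
#' and late October, altitudes between lowland and montane sites, a
#' species-specific modal biotope, and compact geographic home ranges
#' on the presence grid. Noise rates put a small fraction of records
#' outside the species' seasonal/altitudinal support, in non-modal
#' biotopes, and outside the home range, as real citizen-science data
#' would.
#'
#' @param n_species Number of species (default 74, the size of the
#'   Czech odonate fauna).
#' @param n_records Number of occurrence records to draw.
#' @param commonality_skew Exponent of the power-law species-frequency
#'   distribution (`p_i` proportional to `i^-skew`); 1 gives the
#'   classic steeply skewed abundance curve.
#' @param support_noise Fraction of records falling outside the
#'   species' seasonal and altitudinal support.
#' @param biotope_noise Fraction of records in non-modal biotopes.
#' @param range_noise Fraction of records outside the species' home
#'   cells.
#' @param bbox Named numeric vector `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` (default: roughly the Czech Republic).
#' @param years Integer vector of calendar years records may fall in.
#' @param seed Integer RNG seed; every generator function is
#'   deterministic given the config.
#' @return A `odo_generator_config` list.
#' @export
generator_config <- function(n_species = 74,
                             n_records = 20000,
                             commonality_skew = 1,
                             support_noise = 0.05,
                             biotope_noise = 0.3,
                             range_noise = 0.05,
                             bbox = c(lat_min = 48.55, lat_max = 51.06,
                                      lon_min = 12.09, lon_max = 18.87),
                             years = 2002:2018,
                             seed = 42) {
  stopifnot(
    n_species >= 1, n_records >= 0,
    support_noise >= 0, support_noise <= 1,
    biotope_noise >= 0, biotope_noise <= 1,
    range_noise >= 0, range_noise <= 1,
    bbox["lat_min"] < bbox["lat_max"], bbox["lon_min"] < bbox["lon_max"]
  )
  structure(
    list(
      n_species = as.integer(n_species), n_records = as.integer(n_records),
      commonality_skew = commonality_skew, support_noise = support_noise,
      biotope_noise = biotope_noise, range_noise = range_noise,
      bbox = bbox, years = as.integer(years), seed = as.integer(seed)
    ),
    class = "odo_generator_config"
  )
}

#' Generate a synthetic expert knowledge base
#'
#' Each species gets a random suborder, a seasonal trapezoid within
#' day-of-year 60-300, an altitude trapezoid within 100-1500 m, per-sex
#' additive colour rows with 1-3 colours at full degree, and per-sex
#' exclusion rows with 0-2 hard exclusions drawn from outside that
#' sex's additive support (so a species never excludes a colour it may
#' show). The similarity matrix is [default_colour_similarity()]. The
#' values are demonstration constants with the right structure, not
#' expert knowledge about any real fauna.
#'
#' @param cfg A [generator_config()].
#' @return A validated `odo_kb` with `cfg$n_species` species.
#' @export
generate_knowledge_base <- function(cfg) {
  cols <- odo_colours()
  withr::with_seed(cfg$seed, {
    species <- purrr::map(seq_len(cfg$n_species), function(i) {
      season <- random_trapezoid(lo = 60, hi = 300,
                                 plateau = c(20, 60), ramp = c(5, 20))
      alt <- random_trapezoid(lo = 100, hi = 1500,
                              plateau = c(100, 400), ramp = c(50, 200))
      colour_rows <- purrr::map(stats::setNames(odo_sexes(), odo_sexes()),
        function(sx) {
          supp <- sample(cols, sample(1:3, 1))
          add <- stats::setNames(rep(0, length(cols)), cols)
          add[supp] <- 1
          n_exc <- sample(0:2, 1)
          exc <- stats::setNames(rep(1, length(cols)), cols)
          pool <- setdiff(cols, supp)
          if (n_exc > 0 && length(pool) > 0) {
            exc[sample(pool, min(n_exc, length(pool)))] <- 0
          }
          list(additive = add, exclusion = exc)
        }
      )
      species_knowledge(
        species_id = sprintf("species_%02d", i),
        suborder = sample(odo_suborders(), 1),
        seasonality = season,
        altitude = alt,
        colours_additive = purrr::map(colour_rows, "additive"),
        colours_exclusion = purrr::map(colour_rows, "exclusion")
      )
    })
  })
  knowledge_base(species)
}

# a trapezoid with integer knots: plateau [b, c] of given length range,
# ramps of given length range, clamped to [lo, hi]
random_trapezoid <- function(lo, hi, plateau, ramp) {
  width <- sample(plateau[1]:plateau[2], 1)
  b <- sample(lo:(hi - width), 1)
  c <- b + width
  a <- max(lo, b - sample(ramp[1]:ramp[2], 1))
  d <- min(hi, c + sample(ramp[1]:ramp[2], 1))
  trapezoid(a, b, c, d)
}

#' Generate synthetic occurrence records
#'
#' Species are drawn from the skewed frequency distribution of the
#' config; each record gets a date uniform within the species' seasonal
#' plateau (or, with probability `support_noise`, outside the support),
#' a location uniform within one of the species' home cells (or, with
#' probability `range_noise`, anywhere in the bounding box), an
#' altitude within the support (or outside, with `support_noise`), a
#' biotope from a species-specific multinomial whose mode carries
#' probability `1 - biotope_noise`, a sex, and an abundance class.
#' Colours are left empty; add them with [augment_colours()].
#'
#' @param kb A knowledge base (typically from
#'   [generate_knowledge_base()]).
#' @param cfg A [generator_config()].
#' @return A records tibble of `cfg$n_records` rows.
#' @export
generate_records <- function(kb, cfg) {
  ids <- names(kb$species)
  n_sp <- length(ids)
  n <- cfg$n_records
  biotopes <- kb$biotope_vocabulary
  grid <- grid_config()
  # per-species parameter vectors for vectorised sampling
  sa <- purrr::map_dbl(kb$species, ~ .x$seasonality$a)
  sb <- purrr::map_dbl(kb$species, ~ .x$seasonality$b)
  sc <- purrr::map_dbl(kb$species, ~ .x$seasonality$c)
  sd <- purrr::map_dbl(kb$species, ~ .x$seasonality$d)
  aa <- purrr::map_dbl(kb$species, ~ .x$altitude$a)
  ab <- purrr::map_dbl(kb$species, ~ .x$altitude$b)
  ac <- purrr::map_dbl(kb$species, ~ .x$altitude$c)
  ad <- purrr::map_dbl(kb$species, ~ .x$altitude$d)

  withr::with_seed(cfg$seed + 1L, {
    p <- seq_len(n_sp)^(-cfg$commonality_skew)
    p <- p / sum(p)
    modal_biotope <- sample(biotopes, n_sp, replace = TRUE)
    # compact home range: a (2k+1)^2 block of grid cells around a centre
    centre <- gps_to_grid_cell(
      stats::runif(n_sp, cfg$bbox["lat_min"], cfg$bbox["lat_max"]),
      stats::runif(n_sp, cfg$bbox["lon_min"], cfg$bbox["lon_max"]),
      grid
    )
    half_range <- sample(1:4, n_sp, replace = TRUE)

    i <- sample.int(n_sp, n, replace = TRUE, prob = p)
    year <- sample(cfg$years, n, replace = TRUE)

    # day of year: uniform on the seasonal plateau, or (noise) uniform on
    # the complement of the support in [1, 365]
    doy <- sb[i] + floor(stats::runif(n) * (sc[i] - sb[i] + 1))
    noisy <- stats::runif(n) < cfg$support_noise
    lo <- ceiling(sa[i]) # support complement: [1, lo-1] U [hi+1, 365]
    hi <- floor(sd[i])
    u <- floor(stats::runif(n) * (365 - (hi - lo + 1))) + 1
    doy[noisy] <- ifelse(u < lo, u, u + (hi - lo + 1))[noisy]

    # altitude: uniform on the plateau, or outside the support in [0, 1600]
    altitude <- stats::runif(n, ab[i], ac[i])
    noisy <- stats::runif(n) < cfg$support_noise
    ua <- stats::runif(n, 0, 1600 - (ad[i] - aa[i]))
    altitude[noisy] <- ifelse(ua < aa[i], ua, ua + (ad[i] - aa[i]))[noisy]

    # location: uniform inside a random home cell, or anywhere in the box
    dr <- floor(stats::runif(n) * (2 * half_range[i] + 1)) - half_range[i]
    dc <- floor(stats::runif(n) * (2 * half_range[i] + 1)) - half_range[i]
    lat <- grid$lat0 + (centre$row[i] + dr + stats::runif(n)) * grid$dlat
    lon <- grid$lon0 + (centre$col[i] + dc + stats::runif(n)) * grid$dlon
    noisy <- stats::runif(n) < cfg$range_noise
    lat[noisy] <- stats::runif(sum(noisy), cfg$bbox["lat_min"], cfg$bbox["lat_max"])
    lon[noisy] <- stats::runif(sum(noisy), cfg$bbox["lon_min"], cfg$bbox["lon_max"])

    # biotope: the species' modal biotope, or a uniform non-modal one
    biotope <- modal_biotope[i]
    noisy <- stats::runif(n) < cfg$biotope_noise
    other <- floor(stats::runif(n) * (length(biotopes) - 1)) + 1
    other_code <- purrr::map2_chr(other, i,
                                  ~ setdiff(biotopes, modal_biotope[.y])[.x])
    biotope[noisy] <- other_code[noisy]

    recs <- tibble::tibble(
      species_id = ids[i],
      sex = sample(odo_sexes(), n, replace = TRUE),
      date = as.Date(sprintf("%d-01-01", year)) + (doy - 1),
      lat = lat, lon = lon,
      altitude = altitude,
      biotope = biotope,
      count = sample(odo_abundance_classes(), n, replace = TRUE),
      colours = rep(list(character()), n)
    )
  })
  class(recs) <- c("odo_records", class(recs))
  recs
}

#' Assign plausible colours to records
#'
#' Emulates the colour augmentation used to prepare training data: each
#' record without colours receives 1 to `max_colours` colours sampled
#' without replacement from the additive colour support of its
#' species/sex (the colours the species may actually show); records of
#' unknown sex sample from the union of both sexes' supports. A species
#' with empty support leaves the record colourless with a warning.
#'
#' @param records A records tibble.
#' @param kb The knowledge base providing the colour rows.
#' @param max_colours Maximum colours per record (default 3).
#' @param seed Integer RNG seed; the augmentation is deterministic
#'   given it.
#' @return The records tibble with the `colours` list-column filled.
#' @export
augment_colours <- function(records, kb, max_colours = 3, seed) {
  unknown <- setdiff(unique(records$species_id), names(kb$species))
  if (length(unknown)) {
    odo_abort(
      sprintf("records mention species not in the knowledge base: %s",
              paste(utils::head(unknown, 5), collapse = ", ")),
      "odofuzz_input_error"
    )
  }
  supports <- purrr::map(kb$species, function(sp) {
    purrr::map(sp$colours_additive, ~ names(.x)[.x > 0])
  })
  empty_support <- FALSE
  withr::with_seed(seed, {
    records$colours <- purrr::map(seq_len(nrow(records)), function(i) {
      sp <- records$species_id[i]
      sx <- records$sex[i]
      supp <- if (sx %in% odo_sexes()) {
        supports[[sp]][[sx]]
      } else {
        unique(unlist(supports[[sp]]))
      }
      if (length(supp) == 0) {
        empty_support <<- TRUE
        return(character())
      }
      n <- sample.int(min(max_colours, length(supp)), 1)
      supp[sample.int(length(supp), n)]
    })
  })
  if (empty_support) {
    warning("some records left colourless: species/sex with empty additive colour support")
  }
  records
}
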