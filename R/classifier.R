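#' Build an observation query
#'
#' Every field is optional: the classifier works with partial
#' information, and a coefficient whose input is missing is fixed at 1
#' so it does not affect the ranking.
#'
#' @param date Observation date (`Date` or `"YYYY-MM-DD"` string).
#' @param lat,lon WGS84 decimal degrees (supply both or neither).
#' @param altitude Metres above sea level.
#' @param suborder `"anisoptera"` or `"zygoptera"`.
#' @param biotope A biotope code (see [odo_biotopes()]).
#' @param colours Character vector of at most three colour codes.
#' @return An `odo_observation` list.
#' @examples
#' observation(date = "2018-07-01", lat = 50.08, lon = 17.23,
#'             altitude = 430, suborder = "anisoptera",
#'             biotope = "pond", colours = c("red", "brown"))
#' @export
observation <- function(date = NULL, lat = NULL, lon = NULL, altitude = NULL,
                        suborder = NULL, biotope = NULL, colours = NULL) {
  if (!is.null(date)) {
    date <- tryCatch(as.Date(date), error = function(e) NA)
    if (is.na(date)) odo_abort("invalid observation date", "odofuzz_input_error")
  }
  if (xor(is.null(lat), is.null(lon))) {
    odo_abort("lat and lon must be supplied together", "odofuzz_input_error")
  }
  if (!is.null(suborder) && !suborder %in% odo_suborders()) {
    odo_abort("unknown suborder", "odofuzz_input_error")
  }
  if (length(colours) > 3) {
    odo_abort("at most 3 colours may be selected", "odofuzz_input_error")
  }
  if (length(colours) && !all(colours %in% odo_colours())) {
    odo_abort(
      sprintf("unknown colour(s): %s",
              paste(setdiff(colours, odo_colours()), collapse = ", ")),
      "odofuzz_input_error"
    )
  }
  structure(
    list(date = date, lat = lat, lon = lon, altitude = altitude,
         suborder = suborder, biotope = biotope,
         colours = unique(as.character(colours))),
    class = "odo_observation"
  )
}

#' Colour coefficient by composition of fuzzy relations
#'
#' The observer's binary colour selection `in` is composed with the
#' similarity matrix `S` by a sup-min composition, giving each colour a
#' degree `v[c'] = max over selected c of S[c, c']`; composing `v` with
#' the species' additive row `A` gives `w = max over c' of min(v[c'],
#' A[c'])`, which is shifted into `[offset, 1]` as `weight * w +
#' offset`. Independently, the exclusion row `E` (permissibility) is
#' combined over the *selected* colours by an inf-composition `x = min
#' over selected c of E[c]`, so ticking a forbidden colour caps the
#' coefficient at 0 no matter how well other colours match. The result
#' is `min(weight * w + offset, x)`; an empty selection returns 1.
#'
#' @param selected Character vector of selected colour codes (0-3), or a
#'   binary 0/1 vector over `colnames(S)`.
#' @param S Colour-similarity matrix.
#' @param A_col,E_col The species/sex additive and exclusion
#'   (permissibility) colour vectors, named by colour.
#' @param constants A [classifier_constants()] block (only
#'   `additive_weight` and `additive_offset` are used).
#' @return A number in `[0, 1]`.
#' @examples
#' S <- default_colour_similarity()
#' A <- c(yellow = 0, orange = 0, red = 1, green = 0, blue = 0, brown = 0.5, black = 0)
#' E <- c(yellow = 1, orange = 1, red = 1, green = 0, blue = 1, brown = 1, black = 1)
#' colour_coefficient("red", S, A, E)     # matches: full relevance
#' colour_coefficient("green", S, A, E)   # excluded: 0
#' colour_coefficient(character(), S, A, E) # no input: neutral 1
#' @export
colour_coefficient <- function(selected, S, A_col, E_col,
                               constants = classifier_constants()) {
  vocab <- colnames(S)
  if (is.numeric(selected)) {
    if (length(selected) != length(vocab) || !all(selected %in% c(0, 1))) {
      odo_abort("a numeric colour selection must be binary over the vocabulary",
                "odofuzz_input_error")
    }
    selected <- vocab[selected == 1]
  }
  if (length(selected) > 3) {
    odo_abort("at most 3 colours may be selected", "odofuzz_input_error")
  }
  if (!all(selected %in% vocab)) {
    odo_abort("selected colours must be in the vocabulary", "odofuzz_input_error")
  }
  if (length(selected) == 0) {
    return(1)
  }
  if (is.null(names(A_col))) names(A_col) <- vocab
  if (is.null(names(E_col))) names(E_col) <- vocab
  v <- apply(S[selected, , drop = FALSE], 2, max)
  w <- max(pmin(v, A_col[vocab]))
  additive <- constants$additive_weight * w + constants$additive_offset
  x <- min(E_col[selected])
  unname(min(additive, x))
}

#' Individual relevance coefficients
#'
#' Each coefficient maps one observation field onto its documented
#' interval and returns the neutral value 1 when the field is missing:
#' season and altitude rescale the trapezoid membership into
#' `[floor, 1]`; position is 1 when the species has a training record in
#' the query's grid cell and `absent_position` (default 0.5) otherwise;
#' biotope looks up the trained preference in `[0.8, 1]`; suborder is a
#' hard 0/1 match.
#'
#' @param kb_entry A species entry from a knowledge base
#'   (`kb$species[[id]]`).
#' @param date Observation date, or `NULL`.
#' @param floor Lower end of the coefficient interval.
#' @return A number in the documented interval.
#' @export
season_coefficient <- function(kb_entry, date, floor = 0.5) {
  if (is.null(date)) {
    return(1)
  }
  doy <- record_day_of_year(as.Date(date))
  floor + (1 - floor) * trapezoid_membership(kb_entry$seasonality, doy)
}

#' @rdname season_coefficient
#' @param altitude Altitude in metres, or `NULL`.
#' @export
altitude_coefficient <- function(kb_entry, altitude, floor = 0.5) {
  if (is.null(altitude) || is.na(altitude)) {
    return(1)
  }
  floor + (1 - floor) * trapezoid_membership(kb_entry$altitude, altitude)
}

#' @rdname season_coefficient
#' @param model A fitted [fit_model()] object.
#' @param species_id Species identifier.
#' @param lat,lon Query coordinates, or `NULL`.
#' @export
position_coefficient <- function(model, species_id, lat, lon) {
  if (is.null(lat) || is.null(lon)) {
    return(1)
  }
  key <- presence_keys(species_id, lat, lon, model$grid)
  if (key %in% model$class_table$presence_keys) 1 else model$constants$absent_position
}

#' @rdname season_coefficient
#' @param biotope Biotope code, or `NULL`.
#' @export
biotope_coefficient <- function(model, species_id, biotope) {
  if (is.null(biotope) || is.na(biotope)) {
    return(1)
  }
  if (!biotope %in% colnames(model$biotope_pref)) {
    odo_abort(sprintf("unknown biotope code: %s", biotope), "odofuzz_input_error")
  }
  unname(model$biotope_pref[species_id, biotope])
}

#' @rdname season_coefficient
#' @param query_suborder The suborder given by the observer, or `NULL`.
#' @export
suborder_coefficient <- function(kb_entry, query_suborder) {
  if (is.null(query_suborder)) {
    return(1)
  }
  as.numeric(kb_entry$suborder == query_suborder)
}

#' Relevance of one species/sex class
#'
#' The relevance of a class for an observation is the product of the
#' seven coefficients
#' `commonality * suborder * colour * position * altitude * biotope * season`,
#' each in `[0, 1]`, using the sex-specific colour rows. The breakdown
#' is returned alongside the product.
#'
#' @param model A fitted `odo_model`.
#' @param species_id Species identifier (must be in the model).
#' @param sex `"male"` or `"female"`.
#' @param obs An [observation()].
#' @return A one-row tibble: `species_id`, `sex`, `relevance`, and the
#'   seven coefficient columns.
#' @export
relevance <- function(model, species_id, sex, obs) {
  if (!species_id %in% names(model$kb$species)) {
    odo_abort(sprintf("unknown species: %s", species_id), "odofuzz_input_error")
  }
  sex <- match.arg(sex, odo_sexes())
  ranked <- classify(model, obs)
  ranked[ranked$species_id == species_id & ranked$sex == sex, , drop = FALSE]
}

#' Rank all species/sex classes for an observation
#'
#' Computes the seven-coefficient relevance of every class and returns
#' them sorted by relevance, descending. Ties are broken by commonality
#' (descending), then species id (lexicographic), then male before
#' female, giving a deterministic total order. All classes are
#' returned, including zero-relevance ones; truncation is the caller's
#' choice.
#'
#' @param model A fitted `odo_model`.
#' @param obs An [observation()]; an all-empty observation ranks
#'   classes purely by commonality.
#' @return A tibble (class `odo_ranking`) with one row per species/sex
#'   class: `species_id`, `sex`, `relevance`, and the seven coefficient
#'   columns, sorted by the deterministic order above.
#' @examples
#' cfg <- generator_config(n_species = 4, n_records = 100, seed = 2)
#' kb <- generate_knowledge_base(cfg)
#' model <- fit_model(kb, generate_records(kb, cfg))
#' classify(model, observation(suborder = "anisoptera"))
#' @export
classify <- function(model, obs = observation()) {
  stopifnot(inherits(model, "odo_model"), inherits(obs, "odo_observation"))
  ct <- model$class_table
  n <- length(ct$species_id)
  kk <- model$constants

  season <- if (is.null(obs$date)) rep(1, n) else {
    doy <- record_day_of_year(obs$date)
    kk$season_floor + (1 - kk$season_floor) *
      trapezoid_membership_(ct$season[[1]], ct$season[[2]],
                            ct$season[[3]], ct$season[[4]], rep(doy, n))
  }
  altitude <- if (is.null(obs$altitude) || is.na(obs$altitude)) rep(1, n) else {
    kk$altitude_floor + (1 - kk$altitude_floor) *
      trapezoid_membership_(ct$altitude[[1]], ct$altitude[[2]],
                            ct$altitude[[3]], ct$altitude[[4]],
                            rep(obs$altitude, n))
  }
  suborder <- if (is.null(obs$suborder)) rep(1, n) else {
    as.numeric(ct$suborder == obs$suborder)
  }
  position <- if (is.null(obs$lat)) rep(1, n) else {
    keys <- presence_keys(ct$species_id, obs$lat, obs$lon, model$grid)
    ifelse(keys %in% ct$presence_keys, 1, kk$absent_position)
  }
  biotope <- if (is.null(obs$biotope)) rep(1, n) else {
    if (!obs$biotope %in% colnames(ct$biotope_pref)) {
      odo_abort(sprintf("unknown biotope code: %s", obs$biotope),
                "odofuzz_input_error")
    }
    unname(ct$biotope_pref[, obs$biotope])
  }
  colour <- if (length(obs$colours) == 0) rep(1, n) else {
    S <- model$kb$colour_similarity
    v <- apply(S[obs$colours, , drop = FALSE], 2, max)
    # w per class: max over colours of min(v[c'], A[class, c'])
    w <- apply(sweep_pmin(ct$A, v), 1, max)
    additive <- kk$additive_weight * w + kk$additive_offset
    x <- apply(ct$E[, obs$colours, drop = FALSE], 1, min)
    pmin(additive, x)
  }

  out <- tibble::tibble(
    species_id = ct$species_id,
    sex = ct$sex,
    relevance = ct$commonality * suborder * colour * position *
      altitude * biotope * season,
    commonality = ct$commonality,
    suborder = suborder,
    colour = colour,
    position = position,
    altitude = altitude,
    biotope = biotope,
    season = season
  )
  out <- out[ranking_order(out), , drop = FALSE]
  class(out) <- c("odo_ranking", class(out))
  out
}

# deterministic total order: relevance desc, commonality desc,
# species_id asc, male before female
ranking_order <- function(ranked) {
  order(-ranked$relevance, -ranked$commonality, ranked$species_id,
        match(ranked$sex, odo_sexes()))
}

# min(A[k, j], v[j]) without transposing twice per call
sweep_pmin <- function(A, v) {
  pmin(A, matrix(v, nrow = nrow(A), ncol = length(v), byrow = TRUE))
}

#' Collapse the ranking over sexes
#'
#' Per-species relevance is the maximum over its two sex classes;
#' the result is re-sorted under the same tie-break rule (minus sex).
#'
#' @param ranked A ranking from [classify()].
#' @return A tibble with one row per species: `species_id`,
#'   `relevance`, `commonality`.
#' @export
collapse_sexes <- function(ranked) {
  out <- ranked |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      relevance = max(.data$relevance),
      commonality = max(.data$commonality),
      .groups = "drop"
    )
  out[order(-out$relevance, -out$commonality, out$species_id), , drop = FALSE]
}

#' Plot a ranking
#'
#' Horizontal bar chart of the top classes by relevance.
#'
#' @param object An `odo_ranking` from [classify()].
#' @param top Number of classes to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odo_ranking
#' @export
autoplot.odo_ranking <- function(object, top = 15, ...) {
  df <- utils::head(object, top)
  df$label <- paste(df$species_id, df$sex)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$relevance,
    y = stats::reorder(.data$label, .data$relevance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relevance", y = NULL,
                  title = sprintf("Top %d species/sex classes", nrow(df))) +
    ggplot2::theme_minimal()
}
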