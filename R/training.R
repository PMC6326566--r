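#' Classifier constants
#'
#' The tunable constants of the relevance formula, with the published
#' defaults: the additive colour branch is `0.7 * w + 0.3` (so it ranges
#' over `[0.3, 1]`), species absent from the query's grid cell score 0.5,
#' biotope preferences live in `[0.8, 1]`, and season/altitude
#' memberships are rescaled into `[0.5, 1]`. `commonality_floor` lifts
#' the commonality of species unseen in training (default 0: such
#' species get relevance 0).
#'
#' @param additive_weight,additive_offset Slope and offset of the
#'   additive colour branch; their sum must not exceed 1 so the branch
#'   stays within `[0, 1]`.
#' @param absent_position Position coefficient for species without a
#'   training record in the query cell.
#' @param biotope_floor Lower end of the biotope-preference interval.
#' @param season_floor,altitude_floor Lower ends of the season/altitude
#'   coefficient intervals.
#' @param commonality_floor Minimum commonality, in `[0, 1)`.
#' @return A `odo_constants` list.
#' @export
classifier_constants <- function(additive_weight = 0.7,
                                 additive_offset = 0.3,
                                 absent_position = 0.5,
                                 biotope_floor = 0.8,
                                 season_floor = 0.5,
                                 altitude_floor = 0.5,
                                 commonality_floor = 0) {
  k <- list(
    additive_weight = additive_weight, additive_offset = additive_offset,
    absent_position = absent_position, biotope_floor = biotope_floor,
    season_floor = season_floor, altitude_floor = altitude_floor,
    commonality_floor = commonality_floor
  )
  if (any(unlist(k) < 0) || any(unlist(k) > 1)) {
    odo_abort("classifier constants must lie in [0, 1]", "odofuzz_schema_error")
  }
  if (additive_weight + additive_offset > 1 + 1e-12) {
    odo_abort("additive_weight + additive_offset must not exceed 1",
              "odofuzz_schema_error")
  }
  structure(k, class = "odo_constants")
}

#' Commonality of each species
#'
#' Commonality is the species' record count divided by the count of the
#' most frequent species in the training data, so the most frequent
#' species scores 1 and unseen species score 0.
#'
#' @param records A records tibble.
#' @param species_ids Optional character vector of ids to report
#'   (unseen ids get 0); defaults to the species present in `records`.
#' @return A named numeric vector in `[0, 1]`.
#' @examples
#' recs <- tibble::tibble(species_id = c(rep("a", 10), rep("b", 5)))
#' compute_commonality(recs)
#' @export
compute_commonality <- function(records, species_ids = NULL) {
  counts <- table(records$species_id)
  if (is.null(species_ids)) species_ids <- sort(names(counts))
  out <- stats::setNames(rep(0, length(species_ids)), species_ids)
  if (length(counts)) {
    seen <- intersect(species_ids, names(counts))
    out[seen] <- as.numeric(counts[seen]) / max(counts)
  }
  out
}

#' Presence grid from training records
#'
#' A species is "present" in a grid cell iff at least one training
#' record of that species falls into the cell.
#'
#' @param records A records tibble with `species_id`, `lat`, `lon`.
#' @param grid A [grid_config()].
#' @return A tibble with columns `species_id`, `row`, `col` (one row per
#'   occupied species/cell pair).
#' @export
build_presence_grid <- function(records, grid = grid_config()) {
  cells <- gps_to_grid_cell(records$lat, records$lon, grid)
  dplyr::distinct(tibble::tibble(
    species_id = records$species_id,
    row = cells$row,
    col = cells$col
  ))
}

#' Biotope-preference table from training records
#'
#' For each species the per-biotope record counts are max-normalised
#' (`f = count / modal count`, 0 where the species has no biotoped
#' records) and mapped affinely into `[floor, 1]` as `floor +
#' (1 - floor) * f`, so a species' modal biotope scores 1 and an
#' unrecorded biotope scores the floor.
#'
#' @param records A records tibble (`biotope` may be `NA`).
#' @param species_ids Species ids to include (rows); defaults to those
#'   present in `records`.
#' @param biotope_vocabulary Biotope codes (columns).
#' @param floor Lower end of the preference interval, default 0.8.
#' @return A numeric matrix `species x biotope` with values in
#'   `[floor, 1]`.
#' @export
build_biotope_table <- function(records,
                                species_ids = NULL,
                                biotope_vocabulary = odo_biotopes(),
                                floor = 0.8) {
  if (is.null(species_ids)) species_ids <- sort(unique(records$species_id))
  pref <- matrix(floor,
    nrow = length(species_ids), ncol = length(biotope_vocabulary),
    dimnames = list(species_ids, biotope_vocabulary)
  )
  with_biotope <- records[!is.na(records$biotope) &
                            records$species_id %in% species_ids, , drop = FALSE]
  if (nrow(with_biotope)) {
    counts <- table(factor(with_biotope$species_id, levels = species_ids),
                    factor(with_biotope$biotope, levels = biotope_vocabulary))
    row_max <- apply(counts, 1, max)
    f <- counts / pmax(row_max, 1) # species with no biotoped records keep f = 0
    pref <- floor + (1 - floor) * unclass(f)
  }
  pref
}

#' Fit the classification model
#'
#' Binds a knowledge base to the three data-driven tables (commonality,
#' presence grid, biotope preferences) computed from training records.
#' Records whose species is not in the knowledge base are excluded with
#' a warning and counted in the fit report (`attr(model, "fit_report")`).
#'
#' @param kb A validated [knowledge_base()].
#' @param records Training records tibble.
#' @param grid A [grid_config()].
#' @param constants A [classifier_constants()] block.
#' @return An object of class `odo_model`.
#' @examples
#' cfg <- generator_config(n_species = 5, n_records = 200, seed = 1)
#' kb <- generate_knowledge_base(cfg)
#' recs <- generate_records(kb, cfg)
#' model <- fit_model(kb, recs)
#' model
#' @export
fit_model <- function(kb, records, grid = grid_config(),
                      constants = classifier_constants()) {
  kb <- validate_knowledge_base(kb)
  species_ids <- purrr::map_chr(kb$species, "species_id")
  known <- records$species_id %in% species_ids
  if (!any(known) && nrow(records) > 0) {
    odo_abort("no training record matches any knowledge-base species",
              "odofuzz_fit_error")
  }
  n_excluded <- sum(!known)
  if (n_excluded > 0) {
    excluded_ids <- sort(unique(records$species_id[!known]))
    warning(sprintf(
      "%d record(s) of %d unknown species excluded from training: %s",
      n_excluded, length(excluded_ids),
      paste(utils::head(excluded_ids, 5), collapse = ", ")
    ))
    records <- records[known, , drop = FALSE]
  }

  commonality <- compute_commonality(records, species_ids)
  commonality <- pmax(commonality, constants$commonality_floor)
  presence <- build_presence_grid(records, grid)
  biotope_pref <- build_biotope_table(
    records, species_ids, kb$biotope_vocabulary, constants$biotope_floor
  )

  model <- structure(
    list(
      kb = kb,
      commonality = commonality,
      presence = presence,
      biotope_pref = biotope_pref,
      grid = grid,
      constants = constants
    ),
    class = "odo_model"
  )
  model$class_table <- build_class_table(model)
  attr(model, "fit_report") <- tibble::tibble(
    n_records = nrow(records),
    n_excluded = n_excluded,
    n_species = length(species_ids)
  )
  model
}

# Precomputed per-class (species x sex) lookup tables so classify() is a
# handful of vectorised operations over all 2 * n_species classes.
build_class_table <- function(model) {
  kb <- model$kb
  sp <- unname(kb$species)
  ids <- purrr::map_chr(sp, "species_id")
  n <- length(sp)
  sexes <- rep(odo_sexes(), each = n)
  idx <- rep(seq_len(n), times = 2)
  A <- do.call(rbind, purrr::map2(idx, sexes, ~ sp[[.x]]$colours_additive[[.y]]))
  E <- do.call(rbind, purrr::map2(idx, sexes, ~ sp[[.x]]$colours_exclusion[[.y]]))
  list(
    species_id = ids[idx],
    sex = sexes,
    suborder = purrr::map_chr(sp, "suborder")[idx],
    commonality = unname(model$commonality[ids])[idx],
    season = purrr::map(c("a", "b", "c", "d"),
                        ~ purrr::map_dbl(sp, function(s) s$seasonality[[.x]])[idx]),
    altitude = purrr::map(c("a", "b", "c", "d"),
                          ~ purrr::map_dbl(sp, function(s) s$altitude[[.x]])[idx]),
    A = A,
    E = E,
    biotope_pref = model$biotope_pref[ids, , drop = FALSE][idx, , drop = FALSE],
    presence_keys = paste(model$presence$species_id, model$presence$row,
                          model$presence$col, sep = "|")
  )
}

#' @export
print.odo_model <- function(x, ...) {
  cat(sprintf(
    "<odo_model: %d species (%d classes), %d occupied grid cells, grid %gx%g deg>\n",
    length(x$kb$species), 2L * length(x$kb$species),
    nrow(x$presence), x$grid$dlat, x$grid$dlon
  ))
  invisible(x)
}

#' Tidy a fitted model into a per-species coefficient table
#'
#' @param x An `odo_model`.
#' @param ... Unused.
#' @return A tibble with one row per species: commonality, number of
#'   occupied grid cells, and the modal biotope.
#' @method tidy odo_model
#' @export
tidy.odo_model <- function(x, ...) {
  cells <- dplyr::count(x$presence, .data$species_id, name = "n_cells")
  tibble::tibble(
    species_id = names(x$commonality),
    suborder = purrr::map_chr(x$kb$species[names(x$commonality)], "suborder"),
    commonality = unname(x$commonality),
    modal_biotope = colnames(x$biotope_pref)[apply(x$biotope_pref, 1, which.max)]
  ) |>
    dplyr::left_join(cells, by = "species_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L))
}

#' @rdname tidy.odo_model
#' @return `glance()`: a one-row tibble with model-level counts.
#' @method glance odo_model
#' @export
glance.odo_model <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$kb$species),
    n_classes = 2L * length(x$kb$species),
    n_presence_cells = nrow(x$presence),
    mean_commonality = mean(x$commonality)
  )
}

# ---- model serialization ---------------------------------------------------

#' Save and load fitted models
#'
#' The model is written as a single JSON file embedding the full
#' knowledge base (with a content hash for provenance), the three
#' trained tables, the grid and the constants. Loading reconstructs an
#' identical model; no timestamps enter the file, so outputs are
#' diffable.
#'
#' @param model An `odo_model`.
#' @param path Output path (JSON).
#' @return `write_model()`: `path` invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  kb_doc <- kb_to_list(model$kb)
  doc <- list(
    format = "odofuzz_model",
    version = "1.0",
    kb = kb_doc,
    kb_hash = kb_hash(kb_doc),
    commonality = as.list(model$commonality),
    presence = list(
      species_id = model$presence$species_id,
      row = model$presence$row,
      col = model$presence$col
    ),
    biotope_pref = list(
      species = rownames(model$biotope_pref),
      biotopes = colnames(model$biotope_pref),
      values = apply(model$biotope_pref, 1, as.list, simplify = FALSE)
    ),
    grid = unclass(model$grid),
    constants = unclass(model$constants)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    odo_abort(sprintf("model file not found: %s", path), "odofuzz_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "odofuzz_model")) {
    odo_abort(sprintf("not a model file: %s", path), "odofuzz_io_error")
  }
  kb <- kb_from_list(doc$kb)
  bp <- doc$biotope_pref
  biotope_pref <- do.call(rbind, purrr::map(bp$values, unlist))
  dimnames(biotope_pref) <- list(unlist(bp$species), unlist(bp$biotopes))
  model <- structure(
    list(
      kb = kb,
      commonality = unlist(doc$commonality),
      presence = tibble::tibble(
        species_id = as.character(unlist(doc$presence$species_id)),
        row = as.integer(unlist(doc$presence$row)),
        col = as.integer(unlist(doc$presence$col))
      ),
      biotope_pref = biotope_pref,
      grid = do.call(grid_config, doc$grid),
      constants = do.call(classifier_constants, doc$constants)
    ),
    class = "odo_model"
  )
  model$class_table <- build_class_table(model)
  model
}

# order-insensitive content hash of the serialized kb (no external digest
# dependency: numbers are canonicalised through JSON then summed as a
# simple polynomial rolling hash over bytes)
kb_hash <- function(kb_doc) {
  bytes <- utf8ToInt(jsonlite::toJSON(kb_doc, auto_unbox = TRUE, digits = I(17)))
  h <- 0
  for (byte in bytes) h <- (h * 31 + byte) %% 2147483647
  sprintf("%d", h)
}
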