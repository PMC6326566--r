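#' Assemble an expert knowledge base
#'
#' The knowledge base holds the per-species expert knowledge the classifier
#' composes with user input: the suborder, a seasonality trapezoid
#' (day-of-year), an altitude trapezoid (metres), and per-sex colour rows
#' of two relations: an *additive* row `A` (degree in `[0,1]` to which the
#' species may show each colour) and an *exclusion* row `E`, stored as
#' **permissibility** (1 = the colour carries no penalty, 0 = observing
#' the colour rules the class out). It also carries the colour-similarity
#' matrix `S` and the colour and biotope vocabularies.
#'
#' @param species A list of entries built by [species_knowledge()], or a
#'   single such entry.
#' @param colour_similarity Symmetric matrix with unit diagonal and values
#'   in `[0,1]`, dimension `n_colours x n_colours`. Default
#'   [default_colour_similarity()].
#' @param biotope_vocabulary Character vector of biotope codes
#'   (default [odo_biotopes()], 15 entries).
#' @param colour_vocabulary Character vector of colour codes
#'   (default [odo_colours()], 7 entries).
#' @return An object of class `odo_kb`.
#' @seealso [read_knowledge_base()], [write_knowledge_base()],
#'   [generate_knowledge_base()]
#' @examples
#' kb <- knowledge_base(list(
#'   species_knowledge(
#'     "calopteryx_splendens", "zygoptera",
#'     seasonality = trapezoid(120, 150, 230, 260),
#'     altitude = trapezoid(100, 150, 500, 700),
#'     colours_additive = list(male = c(blue = 1), female = c(green = 1)),
#'     colours_exclusion = list(male = c(red = 0), female = c(red = 0))
#'   )
#' ))
#' kb
#' @export
knowledge_base <- function(species,
                           colour_similarity = default_colour_similarity(),
                           biotope_vocabulary = odo_biotopes(),
                           colour_vocabulary = odo_colours()) {
  if (inherits(species, "odo_species_knowledge")) species <- list(species)
  kb <- structure(
    list(
      species = species,
      colour_similarity = colour_similarity,
      biotope_vocabulary = biotope_vocabulary,
      colour_vocabulary = colour_vocabulary,
      schema_version = "1.0"
    ),
    class = "odo_kb"
  )
  validate_knowledge_base(kb)
}

#' Describe one species for the knowledge base
#'
#' @param species_id Unique species identifier (string).
#' @param suborder `"anisoptera"` or `"zygoptera"`.
#' @param seasonality,altitude [trapezoid()] fuzzy sets on day-of-year
#'   (1-366) and metres respectively.
#' @param colours_additive,colours_exclusion Named lists with elements
#'   `male` and `female`; each a named numeric vector over (a subset of)
#'   the colour vocabulary. Unnamed colours default to 0 in the additive
#'   row and to 1 (fully permissible) in the exclusion row.
#' @return An object of class `odo_species_knowledge`.
#' @export
species_knowledge <- function(species_id, suborder, seasonality, altitude,
                              colours_additive, colours_exclusion = list()) {
  structure(
    list(
      species_id = species_id,
      suborder = suborder,
      seasonality = seasonality,
      altitude = altitude,
      colours_additive = colours_additive,
      colours_exclusion = colours_exclusion
    ),
    class = "odo_species_knowledge"
  )
}

# expand a sparse named colour vector to the full vocabulary
expand_colour_vector <- function(x, vocab, default) {
  v <- rep(default, length(vocab))
  names(v) <- vocab
  if (length(x)) {
    x <- unlist(x)
    bad <- setdiff(names(x), vocab)
    if (length(bad)) {
      odo_abort(
        sprintf("unknown colour(s): %s", paste(bad, collapse = ", ")),
        "odofuzz_schema_error"
      )
    }
    v[names(x)] <- as.numeric(x)
  }
  v
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: unique species ids, valid suborders,
#' ordered trapezoid knots, colour degrees in `[0,1]` over the exact
#' vocabulary for both sexes, and a symmetric unit-diagonal similarity
#' matrix. Errors name the offending species and field.
#'
#' @param kb An `odo_kb` object.
#' @return `kb`, invisibly unchanged, with per-species colour vectors
#'   expanded to the full vocabulary.
#' @export
validate_knowledge_base <- function(kb) {
  cols <- kb$colour_vocabulary
  nc <- length(cols)
  S <- kb$colour_similarity
  if (!is.matrix(S) || !all(dim(S) == nc)) {
    odo_abort(sprintf("colour_similarity must be a %dx%d matrix", nc, nc),
              "odofuzz_schema_error")
  }
  if (any(S < 0) || any(S > 1) || any(abs(S - t(S)) > 1e-12) ||
      any(abs(diag(S) - 1) > 1e-12)) {
    odo_abort("colour_similarity must be symmetric with unit diagonal and values in [0,1]",
              "odofuzz_schema_error")
  }
  dimnames(kb$colour_similarity) <- list(cols, cols)
  if (anyDuplicated(kb$biotope_vocabulary)) {
    odo_abort("biotope_vocabulary has duplicate entries", "odofuzz_schema_error")
  }

  ids <- purrr::map_chr(kb$species, "species_id")
  if (anyDuplicated(ids)) {
    odo_abort(
      sprintf("duplicate species_id: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "odofuzz_schema_error"
    )
  }

  kb$species <- purrr::map(kb$species, function(sp) {
    where <- function(field) sprintf("species '%s', field '%s'", sp$species_id, field)
    if (!sp$suborder %in% odo_suborders()) {
      odo_abort(sprintf("%s: must be one of %s", where("suborder"),
                        paste(odo_suborders(), collapse = "/")),
                "odofuzz_schema_error")
    }
    for (field in c("seasonality", "altitude")) {
      fs <- sp[[field]]
      if (!inherits(fs, "odo_trapezoid")) {
        fs <- tryCatch(trapezoid(fs$a, fs$b, fs$c, fs$d),
          error = function(e) odo_abort(
            sprintf("%s: %s", where(field), conditionMessage(e)),
            "odofuzz_schema_error"
          )
        )
      }
      sp[[field]] <- fs
    }
    for (sex in odo_sexes()) {
      for (rel in c("colours_additive", "colours_exclusion")) {
        default <- if (rel == "colours_additive") 0 else 1
        if (rel == "colours_additive" && is.null(sp[[rel]][[sex]])) {
          odo_abort(sprintf("%s: missing", where(paste0(rel, "$", sex))),
                    "odofuzz_schema_error")
        }
        v <- tryCatch(
          expand_colour_vector(sp[[rel]][[sex]], cols, default),
          error = function(e) odo_abort(
            sprintf("%s: %s", where(paste0(rel, "$", sex)), conditionMessage(e)),
            "odofuzz_schema_error"
          )
        )
        if (any(v < 0) || any(v > 1)) {
          odo_abort(sprintf("%s: degrees must lie in [0,1]", where(paste0(rel, "$", sex))),
                    "odofuzz_schema_error")
        }
        sp[[rel]][[sex]] <- v
      }
    }
    sp
  })
  names(kb$species) <- ids
  invisible(kb)
}

#' @export
print.odo_kb <- function(x, ...) {
  cat(sprintf(
    "<odo_kb: %d species (%d classes), %d colours, %d biotopes, schema %s>\n",
    length(x$species), 2L * length(x$species),
    length(x$colour_vocabulary), length(x$biotope_vocabulary),
    x$schema_version
  ))
  invisible(x)
}

#' Tidy a knowledge base into a species table
#'
#' @param x An `odo_kb`.
#' @param ... Unused.
#' @return A tibble with one row per species: id, suborder, and the eight
#'   trapezoid knots.
#' @method tidy odo_kb
#' @export
tidy.odo_kb <- function(x, ...) {
  purrr::map_dfr(x$species, function(sp) {
    tibble::tibble(
      species_id = sp$species_id,
      suborder = sp$suborder,
      season_a = sp$seasonality$a, season_b = sp$seasonality$b,
      season_c = sp$seasonality$c, season_d = sp$seasonality$d,
      altitude_a = sp$altitude$a, altitude_b = sp$altitude$b,
      altitude_c = sp$altitude$c, altitude_d = sp$altitude$d
    )
  })
}

# ---- serialization ---------------------------------------------------------

kb_to_list <- function(kb) {
  list(
    schema_version = kb$schema_version,
    colours = as.list(kb$colour_vocabulary),
    biotopes = as.list(kb$biotope_vocabulary),
    colour_similarity = apply(kb$colour_similarity, 1, as.list, simplify = FALSE),
    species = purrr::map(unname(kb$species), function(sp) {
      list(
        species_id = sp$species_id,
        suborder = sp$suborder,
        seasonality = sp$seasonality[c("a", "b", "c", "d")],
        altitude = sp$altitude[c("a", "b", "c", "d")],
        colours = purrr::map(stats::setNames(odo_sexes(), odo_sexes()), function(sx) {
          add <- sp$colours_additive[[sx]]
          exc <- sp$colours_exclusion[[sx]]
          list(
            additive = as.list(add[add > 0]),
            exclusion = as.list(exc[exc < 1])
          )
        })
      )
    })
  )
}

kb_from_list <- function(doc) {
  if (is.null(doc$schema_version)) {
    odo_abort("knowledge-base file lacks a schema_version field", "odofuzz_schema_error")
  }
  cols <- unlist(doc$colours)
  S <- do.call(rbind, purrr::map(doc$colour_similarity, unlist))
  species <- purrr::map(doc$species, function(sp) {
    species_knowledge(
      species_id = sp$species_id,
      suborder = sp$suborder,
      seasonality = trapezoid_from_list(sp$seasonality, sp$species_id, "seasonality"),
      altitude = trapezoid_from_list(sp$altitude, sp$species_id, "altitude"),
      colours_additive = purrr::map(sp$colours, "additive"),
      colours_exclusion = purrr::map(sp$colours, "exclusion")
    )
  })
  knowledge_base(
    species,
    colour_similarity = S,
    biotope_vocabulary = unlist(doc$biotopes),
    colour_vocabulary = cols
  )
}

trapezoid_from_list <- function(x, species_id, field) {
  tryCatch(
    trapezoid(x$a, x$b, x$c, x$d),
    error = function(e) odo_abort(
      sprintf("species '%s', field '%s': %s", species_id, field, conditionMessage(e)),
      "odofuzz_schema_error"
    )
  )
}

#' Read and write knowledge-base files
#'
#' Knowledge bases are stored as a single YAML (or JSON) document with a
#' required `schema_version` field; colour and biotope codes are lowercase
#' snake_case strings, colour rows are sparse maps (additive degrees
#' default to 0, exclusion permissibilities to 1). A save/load round trip
#' is field-identical.
#'
#' @param path File path; a `.json` extension selects JSON, anything else
#'   is parsed as YAML (of which JSON is a subset).
#' @return `read_knowledge_base()`: a validated `odo_kb`.
#' @export
read_knowledge_base <- function(path) {
  if (!file.exists(path)) {
    odo_abort(sprintf("knowledge-base file not found: %s", path), "odofuzz_io_error")
  }
  doc <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) odo_abort(
      sprintf("cannot parse knowledge-base file %s: %s", path, conditionMessage(e)),
      "odofuzz_io_error"
    )
  )
  kb_from_list(doc)
}

#' @rdname read_knowledge_base
#' @param kb An `odo_kb` object.
#' @return `write_knowledge_base()`: `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  doc <- kb_to_list(kb)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
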