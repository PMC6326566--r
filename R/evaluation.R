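#' Rank of the true class in a classification
#'
#' The core accuracy statistic: the 1-based position of the correct
#' species/sex class in the relevance-sorted list, under the
#' deterministic tie-break. When `true_sex` is `NULL` the list is first
#' collapsed over sexes with [collapse_sexes()] and the rank refers to
#' the species among the per-species list.
#'
#' @param ranked A ranking from [classify()].
#' @param true_species Species id of the observed individual.
#' @param true_sex `"male"`, `"female"`, or `NULL` to ignore sex.
#' @return Integer rank >= 1.
#' @export
rank_of_truth <- function(ranked, true_species, true_sex = NULL) {
  if (is.null(true_sex)) {
    collapsed <- collapse_sexes(ranked)
    pos <- which(collapsed$species_id == true_species)
  } else {
    pos <- which(ranked$species_id == true_species & ranked$sex == true_sex)
  }
  if (length(pos) != 1) {
    odo_abort(
      sprintf("true class %s/%s not found in the ranked list",
              true_species, true_sex %||% "(any sex)"),
      "odofuzz_evaluation_error"
    )
  }
  pos
}

#' Evaluate ranking accuracy on a test set
#'
#' Reproduces the rank-based accuracy protocol: each test record is
#' turned into an observation (date, coordinates, altitude, biotope,
#' colours, and — optionally — the true species' suborder, which a field
#' user can supply), classified against the model, and the position of
#' the true class recorded. Records without observed colours are given
#' 1-3 plausible colours by the seeded augmentation of
#' [augment_colours()]; records without a recorded sex are evaluated
#' with sex ignored for that case.
#'
#' @param model A fitted `odo_model`.
#' @param test_records Records tibble.
#' @param ignore_sex If `TRUE`, every case is ranked among the
#'   per-species (sex-collapsed) list.
#' @param ks Integer vector of cutoffs for top-k probabilities.
#' @param seed Integer seed for the colour augmentation of records that
#'   lack colours (required: the augmentation is part of the protocol
#'   and must be reproducible).
#' @param supply_suborder If `TRUE` (default) the true species'
#'   suborder enters the observation as user input.
#' @return An object of class `odo_rank_metrics`: a list with
#'   `n_cases`, `n_unrankable`, `mean_position`, `median_position`,
#'   `top_k` (named vector), `quantile_95_position`, `histogram`
#'   (tibble of position/count), and the raw `positions`.
#' @examples
#' cfg <- generator_config(n_species = 5, n_records = 300, seed = 3)
#' kb <- generate_knowledge_base(cfg)
#' recs <- augment_colours(generate_records(kb, cfg), kb, seed = 4)
#' split <- stratified_split(recs, 0.2, seed = 5)
#' model <- fit_model(kb, split$train)
#' evaluate(model, split$test, seed = 6)
#' @export
evaluate <- function(model, test_records, ignore_sex = FALSE,
                     ks = c(5, 10, 15), seed, supply_suborder = TRUE) {
  if (nrow(test_records) == 0) {
    odo_abort("empty test set", "odofuzz_evaluation_error")
  }
  suborders <- purrr::map_chr(model$kb$species, "suborder")
  known <- test_records$species_id %in% names(suborders)
  n_unrankable <- sum(!known)
  rankable <- test_records[known, , drop = FALSE]
  if (nrow(rankable) == 0) {
    odo_abort("no test record matches a model species", "odofuzz_evaluation_error")
  }

  # augment colourless records in a canonical order, so the evaluation is
  # invariant to the order of the test records
  needs_colours <- which(purrr::map_int(rankable$colours, length) == 0)
  if (length(needs_colours)) {
    sub <- rankable[needs_colours, , drop = FALSE]
    canon <- order(sub$species_id, sub$sex, as.numeric(sub$date),
                   sub$lat, sub$lon, sub$altitude, method = "radix")
    aug <- augment_colours(sub[canon, , drop = FALSE], model$kb, seed = seed)
    rankable$colours[needs_colours[canon]] <- aug$colours
  }

  positions <- purrr::map_int(seq_len(nrow(rankable)), function(i) {
    rec <- rankable[i, ]
    has_coords <- !is.na(rec$lat) && !is.na(rec$lon)
    obs <- observation(
      date = rec$date,
      lat = if (has_coords) rec$lat else NULL,
      lon = if (has_coords) rec$lon else NULL,
      altitude = if (!is.na(rec$altitude)) rec$altitude else NULL,
      suborder = if (supply_suborder) unname(suborders[rec$species_id]) else NULL,
      biotope = if (!is.na(rec$biotope)) rec$biotope else NULL,
      colours = rec$colours[[1]]
    )
    ranked <- classify(model, obs)
    sex <- if (ignore_sex || !rec$sex %in% odo_sexes()) NULL else rec$sex
    rank_of_truth(ranked, rec$species_id, sex)
  })

  rank_metrics(positions, ks, n_unrankable)
}

rank_metrics <- function(positions, ks = c(5, 10, 15), n_unrankable = 0L) {
  hist <- tibble::tibble(position = sort(unique(positions))) |>
    dplyr::mutate(count = as.integer(table(positions)[as.character(.data$position)]))
  structure(
    list(
      n_cases = length(positions),
      n_unrankable = as.integer(n_unrankable),
      mean_position = mean(positions),
      median_position = stats::median(positions),
      top_k = stats::setNames(
        purrr::map_dbl(ks, ~ mean(positions <= .x)),
        paste0("top_", ks)
      ),
      quantile_95_position = empirical_quantile_position(positions, 0.95),
      histogram = hist,
      positions = positions
    ),
    class = "odo_rank_metrics"
  )
}

# smallest position whose cumulative share of cases is >= p
empirical_quantile_position <- function(positions, p) {
  tab <- table(positions)
  cum <- cumsum(tab) / length(positions)
  as.integer(names(cum)[which(cum >= p)[1]])
}

#' @export
print.odo_rank_metrics <- function(x, ...) {
  cat(sprintf("<rank metrics on %d test cases>\n", x$n_cases))
  cat(sprintf("  mean position:   %.2f\n", x$mean_position))
  cat(sprintf("  median position: %g\n", x$median_position))
  for (k in names(x$top_k)) {
    cat(sprintf("  %s probability: %.3f\n",
                gsub("_", "-", k), x$top_k[[k]]))
  }
  cat(sprintf("  95%% of cases within the first %d places\n",
              x$quantile_95_position))
  if (x$n_unrankable > 0) {
    cat(sprintf("  (%d unrankable case(s) excluded)\n", x$n_unrankable))
  }
  invisible(x)
}

#' Tidy rank metrics
#'
#' @param x An `odo_rank_metrics`.
#' @param ... Unused.
#' @return `tidy()`: the position histogram as a tibble;
#'   `glance()`: a one-row tibble of the summary statistics.
#' @method tidy odo_rank_metrics
#' @export
tidy.odo_rank_metrics <- function(x, ...) {
  x$histogram
}

#' @rdname tidy.odo_rank_metrics
#' @method glance odo_rank_metrics
#' @export
glance.odo_rank_metrics <- function(x, ...) {
  tibble::as_tibble(c(
    list(
      n_cases = x$n_cases,
      mean_position = x$mean_position,
      median_position = x$median_position
    ),
    as.list(x$top_k),
    list(quantile_95_position = x$quantile_95_position)
  ))
}

#' Histogram of the positions of correct classifications
#'
#' @param object An `odo_rank_metrics`.
#' @param max_position Right edge of the plot (default: the 99th
#'   percentile position).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odo_rank_metrics
#' @export
autoplot.odo_rank_metrics <- function(object, max_position = NULL, ...) {
  df <- object$histogram
  if (is.null(max_position)) {
    max_position <- empirical_quantile_position(object$positions, 0.99)
  }
  df <- df[df$position <= max_position, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "position of the correct classification",
      y = "test cases",
      title = "Positions of correct classifications in the relevance-sorted list"
    ) +
    ggplot2::theme_minimal()
}

#' Temporal hold-out split
#'
#' Splits records by year: the last `n_years` calendar years present in
#' the data form the test set, everything earlier the training set.
#' Used to check robustness against temporal distribution shift.
#'
#' @param records A records tibble with a `date` column.
#' @param n_years Number of most recent years to hold out.
#' @return A list with elements `train` and `test`.
#' @export
temporal_holdout <- function(records, n_years) {
  if (nrow(records) == 0) {
    odo_abort("no records to split", "odofuzz_evaluation_error")
  }
  years <- record_year(records$date)
  cutoff <- max(years) - n_years
  test <- records[years > cutoff, , drop = FALSE]
  train <- records[years <= cutoff, , drop = FALSE]
  if (nrow(train) == 0) {
    odo_abort("temporal hold-out leaves no training records", "odofuzz_evaluation_error")
  }
  if (nrow(test) == 0) {
    odo_abort("temporal hold-out leaves no test records", "odofuzz_evaluation_error")
  }
  list(train = train, test = test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
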