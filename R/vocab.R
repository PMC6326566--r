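#' Controlled vocabularies
#'
#' The classifier works over fixed vocabularies: seven body colours an
#' observer can report, fifteen biotope (habitat) categories, and the two
#' odonate suborders. Vocabulary entries are lowercase snake_case strings.
#'
#' The biotope list holds fourteen named habitat categories plus one
#' reserved slot (`other`), giving the fifteen categories the field app
#' exposes; [knowledge_base()] validates against the vocabulary actually
#' supplied, so alternative lists of a different length can be used.
#'
#' @return A character vector of vocabulary codes.
#' @examples
#' odo_colours()
#' odo_biotopes()
#' @export
odo_colours <- function() {
  c("yellow", "orange", "red", "green", "blue", "brown", "black")
}

#' @rdname odo_colours
#' @export
odo_biotopes <- function() {
  c(
    "lake", "puddle", "canal", "garden_pool", "quarry", "wetland",
    "brook", "headwaters_and_spring", "organic_soil_wetland", "pond",
    "river", "oxbow_lake", "reservoir_in_valley", "terrestrial_habitat",
    "other"
  )
}

#' @rdname odo_colours
#' @export
odo_suborders <- function() {
  c("anisoptera", "zygoptera")
}

#' @rdname odo_colours
#' @export
odo_sexes <- function() {
  c("male", "female")
}

#' Abundance classes for specimen counts
#'
#' Counts are recorded either as an exact positive integer or as one of
#' these abundance classes. They are stored with each record but do not
#' enter the relevance score.
#'
#' @return Character vector of abundance class labels.
#' @export
odo_abundance_classes <- function() {
  c("1", "2-5", "6-10", "11-20", "21-50", "51-100", "100+")
}

#' Default colour-similarity matrix
#'
#' A symmetric 7x7 matrix with unit diagonal encoding perceptual
#' similarity between reportable colours, so colours the observer did not
#' tick still contribute through their similarity to a ticked colour.
#' Off-diagonal values are demonstration constants (red~orange 0.5,
#' blue~green 0.3, all other pairs 0), not expert-elicited values.
#'
#' @return A 7x7 numeric matrix with dimnames `odo_colours()`.
#' @examples
#' default_colour_similarity()["red", "orange"]
#' @export
default_colour_similarity <- function() {
  cols <- odo_colours()
  S <- diag(length(cols))
  dimnames(S) <- list(cols, cols)
  S["red", "orange"] <- S["orange", "red"] <- 0.5
  S["blue", "green"] <- S["green", "blue"] <- 0.3
  S
}

# internal: stop with a classed condition so callers/tests can be specific
odo_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "odofuzz_error"))
}
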