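test_that("colour coefficient follows the composition semantics", {
  S <- diag(7)
  dimnames(S) <- list(odo_colours(), odo_colours())
  A <- c(yellow = 0, orange = 0, red = 1, green = 0, blue = 0, brown = 0, black = 0)
  E_open <- stats::setNames(rep(1, 7), odo_colours())

  # empty selection is neutral
  expect_equal(colour_coefficient(character(), S, A, E_open), 1)
  # perfect additive match with no exclusion: 0.7 * 1 + 0.3 = 1
  expect_equal(colour_coefficient("red", S, A, E_open), 1)
  # no additive support: the offset floor 0.3
  expect_equal(colour_coefficient("blue", S, A, E_open), 0.3)
  # a selected colour with permissibility 0 caps the result at 0
  E_shut <- E_open
  E_shut["red"] <- 0
  expect_equal(colour_coefficient("red", S, A, E_shut), 0)
  # similarity bleeds support onto unselected colours
  S2 <- default_colour_similarity() # red~orange 0.5
  expect_equal(colour_coefficient("orange", S2, A, E_open), 0.7 * 0.5 + 0.3)
  # partial permissibility caps below the additive branch
  E_half <- E_open
  E_half["red"] <- 0.4
  expect_equal(colour_coefficient("red", S2, A, E_half), 0.4)
})

test_that("colour coefficient rejects malformed selections", {
  S <- default_colour_similarity()
  A <- E <- stats::setNames(rep(1, 7), odo_colours())
  expect_error(colour_coefficient(c("red", "blue", "green", "black"), S, A, E),
               class = "odofuzz_input_error")
  expect_error(colour_coefficient("mauve", S, A, E),
               class = "odofuzz_input_error")
  expect_error(colour_coefficient(rep(0.5, 7), S, A, E),
               class = "odofuzz_input_error")
})

test_that("colour coefficient agrees exactly with the explicit-loop oracle", {
  withr::with_seed(55, {
    for (i in 1:300) {
      S <- random_similarity()
      n_classes <- sample(1:20, 1)
      sel <- random_binary_selection()
      for (k in seq_len(n_classes)) {
        A <- stats::runif(7)
        E <- stats::runif(7)
        names(A) <- names(E) <- odo_colours()
        expect_identical(
          colour_coefficient(sel, S, A, E),
          unname(brute_colour_coefficient(sel, S, A, E))
        )
      }
    }
  })
})

test_that("season, altitude, suborder and biotope coefficients map their fields", {
  model <- toy_model()
  sp <- model$kb$species$aeshna_demo # season (120,150,220,250), alt (200,300,800,1000)

  expect_equal(season_coefficient(sp, as.Date("2010-07-01")), 1) # doy 182, plateau
  expect_equal(season_coefficient(sp, as.Date("2010-01-15")), 0.5) # outside
  expect_equal(season_coefficient(sp, as.Date("2010-05-15")), 0.5 + 0.5 * 0.5) # doy 135
  expect_equal(season_coefficient(sp, NULL), 1)

  expect_equal(altitude_coefficient(sp, 500), 1)
  expect_equal(altitude_coefficient(sp, 50), 0.5)
  expect_equal(altitude_coefficient(sp, 250), 0.75)
  expect_equal(altitude_coefficient(sp, NULL), 1)

  expect_equal(suborder_coefficient(sp, "anisoptera"), 1)
  expect_equal(suborder_coefficient(sp, "zygoptera"), 0)
  expect_equal(suborder_coefficient(sp, NULL), 1)

  expect_equal(biotope_coefficient(model, "aeshna_demo", "pond"), 1)
  expect_equal(biotope_coefficient(model, "aeshna_demo", "lake"), 0.8)
  expect_equal(biotope_coefficient(model, "aeshna_demo", NULL), 1)
  expect_error(biotope_coefficient(model, "aeshna_demo", "moonbase"),
               class = "odofuzz_input_error")
})

test_that("position coefficient reads the presence grid", {
  model <- toy_model() # all training records at (50.0, 15.0)
  expect_equal(position_coefficient(model, "aeshna_demo", 50.0, 15.0), 1)
  # a neighbouring cell scores the absent value
  expect_equal(position_coefficient(model, "aeshna_demo", 50.15, 15.0), 0.5)
  expect_equal(position_coefficient(model, "aeshna_demo", NULL, NULL), 1)
})

test_that("relevance is the product of the seven independent coefficients", {
  model <- toy_model()
  obs <- observation(
    date = "2010-05-15", lat = 50.0, lon = 15.0, altitude = 250,
    suborder = "anisoptera", biotope = "river", colours = c("blue", "brown")
  )
  ranked <- classify(model, obs)
  for (i in seq_len(nrow(ranked))) {
    row <- ranked[i, ]
    sp <- model$kb$species[[row$species_id]]
    expect_equal(
      row$relevance,
      unname(model$commonality[row$species_id]) *
        suborder_coefficient(sp, obs$suborder) *
        colour_coefficient(obs$colours, model$kb$colour_similarity,
                           sp$colours_additive[[row$sex]],
                           sp$colours_exclusion[[row$sex]]) *
        position_coefficient(model, row$species_id, obs$lat, obs$lon) *
        altitude_coefficient(sp, obs$altitude) *
        biotope_coefficient(model, row$species_id, obs$biotope) *
        season_coefficient(sp, obs$date),
      tolerance = 1e-15
    )
  }
  one <- relevance(model, "aeshna_demo", "male", obs)
  expect_equal(one$relevance,
               ranked$relevance[ranked$species_id == "aeshna_demo" &
                                  ranked$sex == "male"])
})

test_that("an empty observation ranks purely by commonality", {
  model <- toy_model()
  ranked <- classify(model, observation())
  expect_equal(ranked$relevance, ranked$commonality)
  expect_equal(ranked$species_id[1:2], rep("libellula_demo", 2))
  expect_equal(ranked$sex[1:2], c("male", "female")) # male precedes female on ties
  expect_true(all(diff(ranked$relevance) <= 0))
})

test_that("a wrong suborder annihilates relevance", {
  model <- toy_model()
  ranked <- classify(model, observation(
    suborder = "zygoptera", date = "2010-07-01", colours = "blue"
  ))
  aniso <- ranked$species_id %in% c("aeshna_demo", "libellula_demo")
  expect_true(all(ranked$relevance[aniso] == 0))
  expect_true(all(ranked$relevance[!aniso] > 0))
})

test_that("classify returns every class once in deterministic order", {
  model <- toy_model()
  obs <- observation(date = "2010-06-20", colours = "red")
  ranked <- classify(model, obs)
  expect_equal(nrow(ranked), 6)
  expect_equal(
    sort(paste(ranked$species_id, ranked$sex)),
    sort(paste(rep(names(model$kb$species), 2), rep(c("male", "female"), each = 3)))
  )
  expect_true(all(diff(ranked$relevance) <= 0))
  expect_identical(classify(model, obs), ranked)
})

test_that("removing a field equals forcing its coefficient to one", {
  model <- toy_model()
  full <- list(date = "2010-06-20", lat = 50.0, lon = 15.0, altitude = 400,
               suborder = "anisoptera", biotope = "pond", colours = "blue")
  coef_col <- c(date = "season", lat = "position", altitude = "altitude",
                suborder = "suborder", biotope = "biotope", colours = "colour")
  ranked_full <- classify(model, do.call(observation, full))
  for (field in names(coef_col)) {
    drop <- full
    drop[if (field == "lat") c("lat", "lon") else field] <- NULL
    without <- classify(model, do.call(observation, drop))

    forced <- ranked_full
    forced[[coef_col[[field]]]] <- 1
    forced$relevance <- forced$commonality * forced$suborder * forced$colour *
      forced$position * forced$altitude * forced$biotope * forced$season
    forced <- forced[odofuzz:::ranking_order(forced), ]
    expect_equal(without$species_id, forced$species_id)
    expect_equal(without$sex, forced$sex)
    expect_equal(without$relevance, forced$relevance)
  }
})

test_that("enlarging the colour selection never decreases the sup-min term", {
  withr::with_seed(77, {
    for (i in 1:200) {
      S <- random_similarity()
      A <- stats::runif(7)
      names(A) <- odo_colours()
      E <- stats::setNames(rep(1, 7), odo_colours())
      small <- random_binary_selection(max_ones = 2)
      if (sum(small) == 0) small[sample.int(7, 1)] <- 1
      big <- small
      free <- which(big == 0)
      big[sample(free, 1)] <- 1
      # with E fully permissive the coefficient is monotone in the selection
      expect_gte(colour_coefficient(big, S, A, E),
                 colour_coefficient(small, S, A, E))
    }
  })
})

test_that("collapse_sexes keeps the per-species maximum and reorders", {
  model <- toy_model()
  ranked <- classify(model, observation(colours = "blue"))
  collapsed <- collapse_sexes(ranked)
  expect_equal(nrow(collapsed), 3)
  for (sp in collapsed$species_id) {
    expect_equal(collapsed$relevance[collapsed$species_id == sp],
                 max(ranked$relevance[ranked$species_id == sp]))
  }
  expect_true(all(diff(collapsed$relevance) <= 0))
})

test_that("observations validate their fields", {
  expect_error(observation(lat = 50), class = "odofuzz_input_error")
  expect_error(observation(suborder = "beetle"), class = "odofuzz_input_error")
  expect_error(observation(colours = c("red", "blue", "green", "black")),
               class = "odofuzz_input_error")
  expect_error(observation(colours = "mauve"), class = "odofuzz_input_error")
  expect_error(observation(date = "not-a-date"), class = "odofuzz_input_error")
})

test_that("unknown species or biotopes are input errors at query time", {
  model <- toy_model()
  expect_error(relevance(model, "nessie", "male", observation()),
               class = "odofuzz_input_error")
  expect_error(classify(model, observation(biotope = "moonbase")),
               class = "odofuzz_input_error")
})
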