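---
title: "The fuzzy relevance model behind odofuzz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy relevance model behind odofuzz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odofuzz)
```

## The identification problem

An observer in the field can usually tell a dragonfly (Anisoptera) from a
damselfly (Zygoptera), name up to three dominant colours, and report where
and when the animal was seen — but rarely more. Each of these cues is weak
on its own; together they are surprisingly discriminative, provided the
classifier can cope with *any subset* of them being missing. `odofuzz`
scores every species/sex class by a product of seven coefficients, one per
cue, each mapped into a sub-interval of [0, 1], and fixes a coefficient at
the neutral value 1 whenever its cue was not supplied. A product (rather
than a sum) means a single decisive contradiction — wrong suborder, a
forbidden colour — can veto a class outright, which matches how a human
expert reasons.

## The seven coefficients

Let *o* be a species and consider one sex class of it.

**Commonality** `#o / #max` rewards frequently recorded species. It is the
only coefficient that can be 0 for reasons other than a hard contradiction:
a species absent from the training data can never be proposed. We treat
this as intended behaviour (the training data *define* the candidate pool)
but expose `commonality_floor` in `classifier_constants()` for users who
want rare species to remain reachable; the default is 0.

**Suborder** is a hard 0/1 match, the strongest single cue: it halves the
candidate list.

**Colour** is the heart of the expert system. The observer's selection is a
binary vector **in** over the seven-colour vocabulary (yellow, orange, red,
green, blue, brown, black). Three relations participate:

* *S*, a symmetric colour-similarity matrix with unit diagonal, spreads
  support from selected colours to perceptually similar ones — the sup–min
  composition `v = in ∘ S` gives every colour the degree of its most
  similar selected colour.
* *A*, the additive row, records to what degree the species/sex may show
  each colour; `w = max_c min(v[c], A[c])` is the best supported colour.
  The affine shift `0.7·w + 0.3` keeps even a total colour mismatch at
  0.3 rather than 0: colour perception is noisy, and an amateur's "brown"
  should not eliminate a dark-red species.
* *E*, the exclusion row, is stored as **permissibility**: 1 means the
  colour carries no penalty, 0 means the species must never show it. The
  selected colours are combined by an inf-composition,
  `x = min_{c selected} E[c]`, and the final coefficient is
  `min(0.7·w + 0.3, x)`.

The inf-composition (a Bandler–Kohout-style subproduct) is a deliberate
design choice. A sup–min reading of `in ∘ E` would *raise* the cap when a
forbidden colour is selected — the opposite of what an exclusion list is
for. Storing E as permissibility and taking the minimum over selected
colours is the only orientation under which "the species must not have this
colour" prevents the class from ranking highly, and it makes E's neutral
element (all ones) literally "no exclusions".

**Position** consults a presence grid: the graticule defaults to 6′
latitude × 10′ longitude — the Central European faunistic mapping (KFME)
convention, ≈ 11.1 × 11.9 km at Czech latitudes. A species with a training
record in the query's cell scores 1, otherwise 0.5: absence of evidence is
penalised, but mildly, because occurrence databases undersample. Cells are
half-open `[low, high)`; the index arithmetic carries a guard of 10⁻⁹ cell
widths so that coordinates lying exactly on a representable cell boundary
land in the higher-indexed cell rather than drifting down through
floating-point error. The grid origin is a free convention (the field has
no single standard); only same-cell/different-cell behaviour matters to the
classifier, and both the cell size and origin are configurable via
`grid_config()`.

**Biotope** preferences are trained, not expert-supplied: per species the
biotope counts are max-normalised (`f = count / modal count`) and mapped
affinely onto [0.8, 1], so the modal habitat scores 1 and an unrecorded one
0.8. The mapping from counts into the interval is our choice — the interval
itself is part of the model specification, but the normalisation inside it
was open; max-normalisation gives every species a full-scoring modal
habitat regardless of how many records it has, which keeps the coefficient
comparable across common and rare species.

**Season and altitude** use trapezoidal fuzzy sets (a ≤ b ≤ c ≤ d; 0
outside [a, d], 1 on [b, c], linear ramps), rescaled from [0, 1] into
[0.5, 1]. Trapezoids are evaluated with closed plateaus, so degenerate
ramps (a = b) behave as step edges with membership 1 at the knot.
Seasonality lives on day-of-year 1–366 and is **not** circular: Czech
odonate flight seasons do not wrap the year boundary. This is a documented
limitation — a tropical fauna with year-crossing seasons would need a
circular membership function.

## Ranking and ties

Classes are sorted by relevance, descending. The tie-break — commonality
descending, then species id, then male before female — is not part of the
scientific model; it exists so that every ranking, and therefore every
evaluation metric, is reproducible run-to-run. Coefficients are compared as
exact doubles, with no rounding. `relevance` is stored alongside all seven
multiplicands, and the product identity is enforced by tests to 10⁻¹².

## Training

`fit_model()` derives three tables from training records: commonality, the
presence grid, and the biotope table. Whether to build these from all
historical data or only the post-cutoff subset is the caller's choice:
`filter_from_year(records, 2002)` applies the conventional cutoff (older
records carry less reliable metadata and outdated distributions), and the
model trains on exactly the records it is given. Records of species absent
from the knowledge base are excluded with a warning and counted in the fit
report rather than failing the fit: mixed-provenance occurrence files
routinely contain vagrants and synonyms.

## Evaluation protocol

`evaluate()` converts each test record into an observation (date,
coordinates, altitude, biotope, colours — and, by default, the true
species' suborder, since a field user can tell the suborders apart;
`supply_suborder = FALSE` disables this), classifies it, and records the
rank of the true class. Aggregates: mean and median position, top-k
probabilities (default k = 5, 10, 15 — five list items fit one phone
screen), and the 95th-percentile position, computed as the smallest
position whose cumulative share of cases reaches 0.95 (the empirical CDF
convention). Records lacking a recorded sex are ranked with sexes
collapsed (per-species relevance = max over the two sex classes).

Historical records rarely store colours, so the protocol assigns each
colourless test record 1–3 colours sampled from the true species/sex's
additive support — mirroring how such datasets are augmented in practice.
The augmentation seed is a required argument of `evaluate()` and is applied
over a canonical record ordering, making the metrics invariant to the order
of the test file. `temporal_holdout()` supports the complementary
robustness check of training on all but the last *n* years.

## The synthetic-data generator

`generator_config()` defaults define the study conditions under which the
package demonstrates parameter recovery: 74 species (the size of the Czech
odonate fauna, giving the canonical 148 classes), 20,000 records, a
power-law abundance distribution with exponent 1 (a steep, realistic
rank-abundance curve), seasonal windows inside day 60–300, altitudes inside
100–1500 m, a compact home range of up to 9×9 grid cells per species, and
noise rates of 5% (records outside the seasonal/altitudinal support and
outside the home range) and 30% (records in non-modal biotopes). Each
species/sex gets 1–3 additive colours at full degree and 0–2 hard
exclusions drawn from outside its own additive support — a species never
forbids a colour it may show, which would otherwise poison the augmentation
of its own records. The shipped similarity matrix (red~orange 0.5,
blue~green 0.3, other pairs 0) is a demonstration constant.

What the generator does *not* emulate: real species' identities, the
spatial density gradients of a real national database, observer effort
bias, misidentifications, and colour terms that disagree between observers.
Passing the recovery test therefore shows that the pipeline is internally
consistent — that the classifier recovers structure the generator put in —
not that it attains any particular accuracy on real data. The published
accuracy figures for the real Czech system depend on an unpublished expert
knowledge base (trapezoid corners and colour matrices for all 74 species)
and an unseeded augmentation, and are not reproducible from this package;
the demonstration knowledge base shipped under `inst/extdata/` is
synthetic and clearly labelled as such.

At these conditions (fit on a stratified 80% split, full-input evaluation
on the rest) the test suite requires the mean rank of the true class to
beat 15 of 148 and the top-5 probability to exceed 0.5, and both to beat a
commonality-only baseline strictly; the margins observed are wide (mean
rank ≈ 3 vs ≈ 30 for the baseline). Problem sizes in the routine tests are
smaller (5–25 species, hundreds of records), chosen to exercise every code
path rather than to estimate accuracy.

## Numerical and degenerate-input choices

* Trapezoid evaluation is total: any real input maps to [0, 1].
* An empty training set yields commonality 0 everywhere (and `fit_model()`
  refuses record sets disjoint from the knowledge base).
* `stratified_split()` uses R's banker's rounding on `n × fraction`; a
  species whose share rounds to 0 stays entirely in training, so no
  species is silently lost from the model.
* Model JSON uses 17 significant digits, enough for exact double
  round-trips: a saved and reloaded model classifies identically to the
  original, bit for bit.
* Zero-relevance classes are returned, not hidden; truncation is a
  presentation concern (`--top` in the CLI).

## Known limitations

* Seasonality is non-circular (see above).
* The exclusion semantics are binary in spirit; intermediate
  permissibilities work (`min` handles them) but have no calibrated
  interpretation.
* Abundance classes are parsed and stored but unused: the relevance
  formula has no abundance term.
* The position coefficient ignores neighbouring cells; a record 100 m
  across a cell boundary contributes nothing to the query cell.
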