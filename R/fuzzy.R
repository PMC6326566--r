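#' Trapezoidal fuzzy sets
#'
#' A trapezoidal fuzzy set is defined by four ordered knots
#' `a <= b <= c <= d`: membership is 0 outside `[a, d]`, 1 on the plateau
#' `[b, c]`, and linear on the ramps. Seasonality trapezoids live on
#' day-of-year 1-366; altitude trapezoids on metres. Degenerate ramps
#' (`a == b` and/or `c == d`) are legal and behave as step edges with the
#' plateau closed: `trapezoid_membership(trapezoid(10, 10, 20, 20), 10)`
#' is 1.
#'
#' @param a,b,c,d Numeric knots, `a <= b <= c <= d`.
#' @return An object of class `odo_trapezoid`.
#' @examples
#' fs <- trapezoid(100, 150, 200, 250)
#' trapezoid_membership(fs, c(99, 125, 175, 225, 251))
#' @export
trapezoid <- function(a, b, c, d) {
  knots <- c(a = a, b = b, c = c, d = d)
  if (anyNA(knots) || !is.numeric(knots)) {
    odo_abort("trapezoid knots must be non-missing numbers", "odofuzz_schema_error")
  }
  if (!(a <= b && b <= c && c <= d)) {
    odo_abort(
      sprintf("trapezoid knots must satisfy a <= b <= c <= d (got %g, %g, %g, %g)", a, b, c, d),
      "odofuzz_schema_error"
    )
  }
  structure(as.list(knots), class = "odo_trapezoid")
}

#' @rdname trapezoid
#' @param fs A `odo_trapezoid` (or anything coercible via its `a`..`d` fields).
#' @param x Numeric vector of evaluation points.
#' @return `trapezoid_membership()`: numeric vector in `[0, 1]`, same length as `x`.
#' @export
trapezoid_membership <- function(fs, x) {
  trapezoid_membership_(fs$a, fs$b, fs$c, fs$d, x)
}

# vectorised over x and over the knots (recycled); the workhorse used by
# the classifier on whole class tables at once
trapezoid_membership_ <- function(a, b, c, d, x) {
  m <- numeric(length(x))
  m[x >= b & x <= c] <- 1 # plateau closed, also covers a==b / c==d edges
  up <- x > a & x < b
  if (any(up)) m[up] <- ((x - a) / (b - a))[up]
  dn <- x > c & x < d
  if (any(dn)) m[dn] <- ((d - x) / (d - c))[dn]
  m
}

#' @export
print.odo_trapezoid <- function(x, ...) {
  cat(sprintf(
    "<trapezoid a=%g b=%g c=%g d=%g>\n", x$a, x$b, x$c, x$d
  ))
  invisible(x)
}

#' @export
format.odo_trapezoid <- function(x, ...) {
  sprintf("(%g, %g, %g, %g)", x$a, x$b, x$c, x$d)
}
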