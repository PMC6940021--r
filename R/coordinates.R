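# Coordinate generation along dimensions: linear, monotonic, labeled axes,
# absolute coordinates, and dimensionless ratio coordinates.

.new_coords <- function(values, unit, kind) {
  structure(list(values = values, unit = unit, kind = kind),
            class = "csd_coordinates")
}

#' Coordinates of a linear dimension
#'
#' Evaluates `X[j] = increment * (j - Z) + coordinates_offset` over
#' `j = 0 ... count - 1`. `Z = 0` when `complex_fft` is false; when true,
#' `Z = T/2` with `T = count` for even and `count - 1` for odd counts, so
#' the coordinate at index `Z` is exactly the coordinates offset (the zero
#' frequency after a complex FFT). Output is in the increment's unit.
#'
#' @param dim A linear `csd_dimension`.
#' @return A `csd_coordinates`: numeric `values`, `unit` (`csd_unit`), and
#'   `kind = "linear"`.
#' @export
linear_coordinates <- function(dim) {
  stopifnot(inherits(dim, "csd_dimension"), dim$type == "linear")
  N <- dim$count
  inc <- dim$increment
  u <- inc$unit
  b <- if (is.null(dim$coordinates_offset)) 0
  else .q_value_in(dim$coordinates_offset, u)
  Z <- 0L
  if (isTRUE(dim$complex_fft)) {
    T_ <- if (N %% 2L == 0L) N else N - 1L
    Z <- T_ %/% 2L
  }
  j <- 0:(N - 1L)
  .new_coords(inc$value * (j - Z) + b, u, "linear")
}

#' Coordinates of a monotonic dimension
#'
#' The stored quantities, converted to the unit of the first entry, order
#' preserved.
#'
#' @param dim A monotonic `csd_dimension`.
#' @return A `csd_coordinates` of kind `"monotonic"`.
#' @export
monotonic_coordinates <- function(dim) {
  stopifnot(inherits(dim, "csd_dimension"), dim$type == "monotonic")
  u <- dim$coordinates[[1L]]$unit
  v <- vapply(dim$coordinates, .q_value_in, numeric(1), unit = u)
  .new_coords(v, u, "monotonic")
}

#' Coordinates of a labeled dimension
#'
#' @param dim A labeled `csd_dimension`.
#' @return A `csd_coordinates` with character `values` and no unit.
#' @export
labeled_coordinates <- function(dim) {
  stopifnot(inherits(dim, "csd_dimension"), dim$type == "labeled")
  .new_coords(dim$labels, NULL, "labeled")
}

#' Coordinates of any dimension
#'
#' Dispatches on the dimension subtype.
#' @param dim A `csd_dimension`.
#' @export
dimension_coordinates <- function(dim) {
  switch(dim$type,
         linear = linear_coordinates(dim),
         monotonic = monotonic_coordinates(dim),
         labeled = labeled_coordinates(dim),
         stop("unknown dimension type", call. = FALSE))
}

#' Absolute coordinates
#'
#' Adds the origin offset: `X_abs = X + o`.
#'
#' @param coords A numeric `csd_coordinates`.
#' @param origin_offset A `csd_quantity` (or string) with the coordinates'
#'   dimensionality.
#' @return A `csd_coordinates` in the input unit.
#' @export
absolute_coordinates <- function(coords, origin_offset) {
  stopifnot(inherits(coords, "csd_coordinates"))
  if (coords$kind == "labeled")
    stop("labeled dimensions have no absolute coordinates", call. = FALSE)
  o <- .as_quantity(origin_offset)
  ov <- .q_value_in(o, coords$unit)
  .new_coords(coords$values + ov, coords$unit, coords$kind)
}

#' Dimensionless ratio coordinates
#'
#' Scales coordinates by the difference of origin offset and coordinates
#' offset: `X_ratio = X / (o - b)`. In NMR usage `o` is the spectrometer
#' frequency and `b` the reference frequency; multiplying the ratio by 1e6
#' gives ppm.
#'
#' @param coords A numeric `csd_coordinates`.
#' @param origin_offset,coordinates_offset Quantities with the coordinates'
#'   dimensionality; their difference must be nonzero.
#' @param ppm Return the ratio scaled by 1e6?
#' @return A dimensionless `csd_coordinates`.
#' @export
ratio_coordinates <- function(coords, origin_offset, coordinates_offset,
                              ppm = FALSE) {
  stopifnot(inherits(coords, "csd_coordinates"))
  if (coords$kind == "labeled")
    stop("labeled dimensions have no ratio coordinates", call. = FALSE)
  o <- .q_value_in(.as_quantity(origin_offset), coords$unit)
  b <- .q_value_in(.as_quantity(coordinates_offset), coords$unit)
  den <- o - b
  if (den == 0)
    stop("origin_offset equals coordinates_offset: zero denominator",
         call. = FALSE)
  v <- coords$values / den
  if (ppm) v <- v * 1e6
  .new_coords(v, parse_unit(if (ppm) "ppm" else ""), coords$kind)
}

#' @export
print.csd_coordinates <- function(x, ...) {
  n <- length(x$values)
  shown <- utils::head(x$values, 6L)
  cat("<coordinates> ", x$kind, ", n = ", n, sep = "")
  if (!is.null(x$unit) && nzchar(x$unit$symbol))
    cat(", unit '", x$unit$symbol, "'", sep = "")
  cat("\n  ", paste(format(shown), collapse = ", "),
      if (n > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
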