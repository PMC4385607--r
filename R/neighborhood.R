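#' Circular sampling geometry for local binary patterns
#'
#' A `neighborhood_spec` describes the circularly symmetric neighbour set used
#' by the LBP and local-contrast operators: `P` equally spaced samples on a
#' circle of radius `R` (in pixels) around a centre pixel.
#'
#' @param P Integer number of circular samples; must be greater than 1.
#' @param R Radius of the sampling circle in pixels; must be positive.
#'
#' @return An object of class `neighborhood_spec`, a list with elements `P`
#'   and `R`.
#'
#' @details Raw LBP codes produced under a spec lie in `[0, 2^P - 1]`;
#'   rotation-invariant uniform (riu2) codes lie in `[0, P + 1]`. `P` is
#'   capped at 30 so raw codes stay exactly representable as integers.
#'
#' @examples
#' neighborhood_spec(8, 1)
#' @export
neighborhood_spec <- function(P, R) {
  if (length(P) != 1L || !is.finite(P) || P != round(P) || P <= 1)
    abort("`P` must be a single integer > 1.")
  if (P > 30) abort("`P` must be at most 30.")
  if (length(R) != 1L || !is.finite(R) || R <= 0)
    abort("`R` must be a single positive number.")
  structure(list(P = as.integer(P), R = as.numeric(R)),
            class = "neighborhood_spec")
}

#' @export
print.neighborhood_spec <- function(x, ...) {
  cat(sprintf("<neighborhood_spec> P = %d samples, R = %g px\n", x$P, x$R))
  invisible(x)
}

#' Default neighbourhood geometries
#'
#' The three (P, R) combinations used for feature extraction:
#' (P = 8, R = 1), (P = 12, R = 2) and (P = 16, R = 4).
#'
#' @return A named list of three [neighborhood_spec()] objects.
#' @examples
#' default_specs()
#' @export
default_specs <- function() {
  list(P8_R1  = neighborhood_spec(8, 1),
       P12_R2 = neighborhood_spec(12, 2),
       P16_R4 = neighborhood_spec(16, 4))
}

#' Neighbour sample offsets
#'
#' Coordinates of the `P` circular samples relative to the centre pixel.
#' Sample `p` (p = 0, ..., P-1) sits at `(-R sin(2 pi p / P),
#' R cos(2 pi p / P))`, i.e. the first coordinate is a row offset and the
#' second a column offset, progressing anticlockwise from the pixel directly
#' to the right of the centre.
#'
#' @param spec A [neighborhood_spec()].
#'
#' @return A tibble with columns `p`, `row_offset`, `col_offset` and `P` rows.
#'   Offsets within 1e-9 of an integer are snapped to that integer, so e.g.
#'   the axis-aligned samples of (P = 8, R = 1) are exact integer offsets.
#' @examples
#' neighbor_offsets(neighborhood_spec(8, 1))
#' @export
neighbor_offsets <- function(spec) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  p <- seq_len(spec$P) - 1L
  ang <- 2 * pi * p / spec$P
  dr <- snap_integer(-spec$R * sin(ang))
  dc <- snap_integer(spec$R * cos(ang))
  tibble(p = p, row_offset = dr, col_offset = dc)
}

snap_integer <- function(x, tol = 1e-9) {
  r <- round(x)
  ifelse(abs(x - r) < tol, r, x)
}

#' Sample a circular neighbourhood from a 2D slice
#'
#' Reads the centre gray value and the `P` neighbour gray values around a
#' pixel of a 2D image. Neighbours at integer offsets are read directly;
#' fractional positions are estimated by bilinear interpolation of the four
#' surrounding pixels.
#'
#' @param slice A 2D numeric matrix (rows x columns).
#' @param center Integer vector `c(row, col)` of the centre pixel (1-based).
#' @param spec A [neighborhood_spec()].
#'
#' @return A list of class `neighborhood_sample` with elements `g_c` (centre
#'   gray value) and `g` (numeric vector of the `P` neighbour values in
#'   anticlockwise order).
#' @examples
#' m <- matrix(0:24, 5, 5)
#' sample_neighborhood(m, c(3, 3), neighborhood_spec(8, 1))
#' @export
sample_neighborhood <- function(slice, center, spec) {
  stopifnot(is.matrix(slice), inherits(spec, "neighborhood_spec"))
  r0 <- center[1]; c0 <- center[2]
  if (r0 - spec$R < 1 || r0 + spec$R > nrow(slice) ||
      c0 - spec$R < 1 || c0 + spec$R > ncol(slice))
    abort("Neighborhood disc extends outside the slice bounds.")
  off <- neighbor_offsets(spec)
  g <- bilinear_at(slice, r0 + off$row_offset, c0 + off$col_offset)
  structure(list(g_c = slice[r0, c0], g = g), class = "neighborhood_sample")
}

# Vectorised bilinear interpolation at real-valued (row, col) positions.
# Positions must satisfy 1 <= r <= nrow, 1 <= c <= ncol.
bilinear_at <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  # keep the 2x2 patch in-bounds when a coordinate lands on the last row/col
  r0 <- pmin(r0, nrow(img) - 1L); c0 <- pmin(c0, ncol(img) - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  n <- nrow(img)
  i00 <- (c0 - 1) * n + r0
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + n]; v11 <- img[i00 + n + 1]
  # difference form: exact for constant patches (a flat field interpolates
  # to exactly itself, so tie-breaking at g_p = g_c stays deterministic)
  v00 + fr * (v10 - v00) + fc * (v01 - v00) + fr * fc * (v11 - v10 - v01 + v00)
}
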