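#' Sign-threshold a neighbourhood sample
#'
#' Compares each neighbour gray value against the centre value and returns the
#' binary pattern `b_p = 1` if `g_p - g_c >= 0`, `0` otherwise. Ties
#' (`g_p == g_c`) yield 1.
#'
#' @param sample A `neighborhood_sample` from [sample_neighborhood()], or a
#'   list with elements `g_c` and `g`.
#' @return Integer vector of 0/1 bits `b_0 .. b_{P-1}`.
#' @examples
#' sign_threshold(list(g_c = 3, g = c(5, 5, 5, 5, 1, 1, 1, 1)))
#' @export
sign_threshold <- function(sample) {
  as.integer(sample$g - sample$g_c >= 0)
}

#' Binomially weighted LBP code
#'
#' Collapses a P-bit pattern into the integer `sum_p b_p 2^p`. Note that the
#' weight is `2^p` (bit position), the standard binomial weighting that makes
#' the code unique.
#'
#' @param bits Integer vector of 0/1 bits `b_0 .. b_{P-1}`.
#' @return A single integer in `[0, 2^P - 1]`.
#' @examples
#' lbp_code(rep(1, 8)) # 255
#' @export
lbp_code <- function(bits) {
  sum(bits * 2^(seq_along(bits) - 1))
}

#' Circular bitwise right rotation
#'
#' Rotates the `P`-bit number `x` circularly right by `i` positions: bit 0
#' wraps around to bit `P - 1`.
#'
#' @param x Integer code(s) in `[0, 2^P - 1]`; vectorised.
#' @param i Number of positions to rotate (non-negative integer).
#' @param P Word width in bits.
#' @return Rotated code(s), same length as `x`.
#' @examples
#' lbp_ror(1, 1, 8) # 128
#' @export
lbp_ror <- function(x, i, P) {
  i <- i %% P
  if (i == 0) return(x)
  lo <- x %% 2^i            # the i low bits that wrap to the top
  (x - lo) / 2^i + lo * 2^(P - i)
}

#' Rotation-invariant LBP code
#'
#' Maps a raw LBP code to the minimum over all `P` circular rotations,
#' assigning one unique identifier to each rotation class of patterns.
#'
#' @param x Integer code(s) in `[0, 2^P - 1]`; vectorised.
#' @param P Number of bits.
#' @return The minimal rotation of each code.
#' @examples
#' lbp_ri(128, 8) # 1
#' @export
lbp_ri <- function(x, P) {
  out <- x
  for (i in seq_len(P - 1)) out <- pmin(out, lbp_ror(x, i, P))
  out
}

#' Uniformity of an LBP bit pattern
#'
#' Counts the number of bitwise 0/1 spatial transitions in a circular bit
#' pattern. With `circular = TRUE` (the default) the wrap-around pair
#' `(b_{P-1}, b_0)` is included, the standard circular transition count.
#' With `circular = FALSE` only adjacent pairs in a linear scan of the
#' pattern are counted — the convention matched by the worked examples
#' U(00000011) = 1 and U(10000111) = 2 sometimes quoted for this measure.
#'
#' @param bits Integer vector of 0/1 bits `b_0 .. b_{P-1}`.
#' @param circular Include the wrap-around transition? Default `TRUE`.
#' @return Non-negative integer transition count.
#' @examples
#' lbp_uniformity(c(1, 1, 0, 0, 0, 0, 0, 0))                   # 2 (circular)
#' lbp_uniformity(c(1, 1, 0, 0, 0, 0, 0, 0), circular = FALSE) # 1
#' @export
lbp_uniformity <- function(bits, circular = TRUE) {
  P <- length(bits)
  u <- sum(abs(diff(bits)))
  if (circular) u <- u + abs(bits[P] - bits[1])
  as.integer(u)
}

#' Rotation-invariant uniform (riu2) LBP code
#'
#' Uniform patterns (circular uniformity at most 2) are labelled by their
#' count of 1-bits, giving exactly `P + 1` uniform labels `0 .. P`; all
#' non-uniform patterns collapse into the single miscellaneous label `P + 1`.
#'
#' @param bits Integer vector of 0/1 bits `b_0 .. b_{P-1}`.
#' @return Integer label in `[0, P + 1]`.
#' @examples
#' lbp_riu2(rep(1, 8))        # 8
#' lbp_riu2(rep(c(1, 0), 4))  # 9 (miscellaneous)
#' @export
lbp_riu2 <- function(bits) {
  if (lbp_uniformity(bits) <= 2L) sum(bits) else length(bits) + 1L
}

#' Rotation-invariant local contrast
#'
#' Population variance of the `P` neighbour gray values (centre excluded,
#' divisor `P`): `VAR = (1/P) sum (g_p - mu)^2` with `mu = mean(g_p)`.
#' Invariant against shifts in gray scale, but not against scaling.
#'
#' @param sample A `neighborhood_sample`, or a list with element `g`.
#' @return Non-negative local variance.
#' @examples
#' local_contrast(list(g_c = 0, g = c(0, 0, 0, 0, 2, 2, 2, 2))) # 1
#' @export
local_contrast <- function(sample) {
  g <- sample$g
  mu <- mean(g)
  mean((g - mu)^2)
}
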