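# Independent brute-force oracle for the texture operators: literal
# per-pixel evaluation with its own interpolation and its own bit handling
# (string-based rotations), sharing no code with the package internals.

oracle_bilinear <- function(img, r, c) {
  r1 <- floor(r); c1 <- floor(c)
  if (r1 == nrow(img)) r1 <- r1 - 1
  if (c1 == ncol(img)) c1 <- c1 - 1
  dr <- r - r1; dc <- c - c1
  img[r1, c1] * (1 - dr) * (1 - dc) + img[r1 + 1, c1] * dr * (1 - dc) +
    img[r1, c1 + 1] * (1 - dr) * dc + img[r1 + 1, c1 + 1] * dr * dc
}

oracle_neighbors <- function(img, r0, c0, P, R) {
  sapply(0:(P - 1), function(p) {
    dr <- -R * sin(2 * pi * p / P)
    dc <- R * cos(2 * pi * p / P)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    if (dr == round(dr) && dc == round(dc)) img[r0 + dr, c0 + dc]
    else oracle_bilinear(img, r0 + dr, c0 + dc)
  })
}

oracle_ri_code <- function(bits) {
  P <- length(bits)
  rots <- sapply(0:(P - 1), function(i) {
    b <- if (i == 0) bits else c(bits[(i + 1):P], bits[1:i]) # right shift i
    sum(b * 2^(0:(P - 1)))
  })
  min(rots)
}

oracle_riu2_code <- function(bits) {
  P <- length(bits)
  u <- abs(bits[P] - bits[1]) + sum(abs(diff(bits)))
  if (u <= 2) sum(bits) else P + 1
}

# Per-pixel evaluation over every in-bounds masked pixel of each slice.
oracle_maps <- function(volume, mask, P, R, variant, slice_axis = 3) {
  d <- dim(volume)
  out <- list()
  n <- 0
  for (s in seq_len(d[slice_axis])) {
    sl <- switch(slice_axis, volume[s, , ], volume[, s, ], volume[, , s])
    mk <- switch(slice_axis, mask[s, , ], mask[, s, ], mask[, , s])
    for (r0 in seq_len(nrow(sl))) for (c0 in seq_len(ncol(sl))) {
      if (mk[r0, c0] <= 0) next
      if (r0 - R < 1 || r0 + R > nrow(sl) || c0 - R < 1 || c0 + R > ncol(sl)) next
      g <- oracle_neighbors(sl, r0, c0, P, R)
      bits <- as.integer(g - sl[r0, c0] >= 0)
      code <- if (variant == "ri") oracle_ri_code(bits) else oracle_riu2_code(bits)
      mu <- mean(g)
      n <- n + 1
      out[[n]] <- c(r0, c0, s, code, mean((g - mu)^2))
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("row", "col", "slice", "lbp", "contrast")
  m
}

bits_from_string <- function(s) {
  # "10000111" read left-to-right as the circular sequence s_0 .. s_{P-1}
  as.integer(strsplit(s, "")[[1]])
}

# Small interior-masked random volume used across tests
random_masked_volume <- function(dim3 = c(16, 16, 4), margin = 2, seed = 101) {
  set.seed(seed)
  vol <- array(rnorm(prod(dim3), 100, 10), dim3)
  msk <- array(0, dim3)
  msk[(1 + margin):(dim3[1] - margin), (1 + margin):(dim3[2] - margin), ] <- 1
  list(volume = vol, mask = msk)
}

# distance from point p to the segment [a, b]
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else sum((p - a) * ab) / denom
  t <- min(max(t, 0), 1)
  sqrt(sum((p - a - t * ab)^2))
}
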