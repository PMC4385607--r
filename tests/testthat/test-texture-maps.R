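test_that("constant volumes give the all-ones code and zero contrast everywhere", {
  vol <- array(5, c(10, 10, 2))
  msk <- array(0, dim(vol)); msk[4:7, 4:7, ] <- 1
  ri <- compute_texture_maps(vol, msk, neighborhood_spec(8, 1), "ri")
  expect_true(all(ri$values$lbp == 255))
  expect_true(all(ri$values$contrast == 0))
  riu2 <- compute_texture_maps(vol, msk, neighborhood_spec(8, 1), "riu2")
  expect_true(all(riu2$values$lbp == 8))
})

test_that("a single-voxel interior mask yields exactly one mapped voxel", {
  v <- random_masked_volume()
  msk <- array(0, dim(v$volume)); msk[8, 8, 2] <- 1
  tm <- compute_texture_maps(v$volume, msk, neighborhood_spec(8, 1), "ri")
  expect_equal(nrow(tm$values), 1)
  expect_equal(unlist(tm$values[1, c("i", "j", "k")]), c(i = 8, j = 8, k = 2))
})

test_that("masked voxels whose disc leaves the slice are skipped and tallied", {
  vol <- array(rnorm(12 * 12 * 1), c(12, 12, 1))
  msk <- array(1, dim(vol)) # full mask: a 1-voxel border cannot be mapped at R=1
  tm <- compute_texture_maps(vol, msk, neighborhood_spec(8, 1), "ri")
  expect_equal(nrow(tm$values), 10 * 10)
  expect_equal(tm$n_skipped, 144 - 100)
  expect_error(compute_texture_maps(vol, array(0, dim(vol)),
                                    neighborhood_spec(8, 1)), "empty")
  expect_error(compute_texture_maps(vol, array(1, c(12, 12, 2)),
                                    neighborhood_spec(8, 1)), "dimensions")
})

test_that("maps match a literal per-pixel brute-force evaluation", {
  v <- random_masked_volume(c(16, 16, 4), margin = 3, seed = 202)
  for (variant in c("ri", "riu2")) {
    for (sp in list(neighborhood_spec(8, 1), neighborhood_spec(12, 2))) {
      tm <- compute_texture_maps(v$volume, v$mask, sp, variant)
      want <- oracle_maps(v$volume, v$mask, sp$P, sp$R, variant)
      got <- tm$values[order(tm$values$k, tm$values$j, tm$values$i), ]
      ord <- order(want[, "slice"], want[, "col"], want[, "row"])
      want <- want[ord, ]
      expect_equal(got$lbp, unname(want[, "lbp"]))
      expect_equal(got$contrast, unname(want[, "contrast"]), tolerance = 1e-12)
    }
  }
})

test_that("maps are invariant to gray-scale shifts and LBP to monotone transforms", {
  v <- random_masked_volume(seed = 303)
  sp <- neighborhood_spec(8, 1)
  base <- compute_texture_maps(v$volume, v$mask, sp, "riu2")
  shifted <- compute_texture_maps(v$volume + 42.5, v$mask, sp, "riu2")
  expect_identical(base$values$lbp, shifted$values$lbp)
  expect_equal(base$values$contrast, shifted$values$contrast, tolerance = 1e-9)

  # positive affine maps preserve interpolated sign comparisons
  aff <- compute_texture_maps(3 * v$volume + 7, v$mask, sp, "riu2")
  expect_identical(base$values$lbp, aff$values$lbp)

  # arbitrary strictly increasing transforms are exactly invariant where
  # sampling needs no interpolation (all-integer offsets: P = 4, R = 1)
  sp4 <- neighborhood_spec(4, 1)
  b4 <- compute_texture_maps(v$volume, v$mask, sp4, "riu2")
  m4 <- compute_texture_maps(exp(v$volume / 20), v$mask, sp4, "riu2")
  expect_identical(b4$values$lbp, m4$values$lbp)
})

test_that("rotating a slice by 90 degrees preserves the multiset of ri codes", {
  set.seed(7)
  sl <- matrix(rnorm(20 * 20), 20, 20)
  rot <- t(sl)[, rev(seq_len(20))] # 90-degree rotation
  msk2d <- matrix(0, 20, 20); msk2d[5:16, 5:16] <- 1
  rmsk2d <- t(msk2d)[, rev(seq_len(20))]
  vol <- array(sl, c(20, 20, 1)); msk <- array(msk2d, c(20, 20, 1))
  rvol <- array(rot, c(20, 20, 1)); rmsk <- array(rmsk2d, c(20, 20, 1))
  a <- compute_texture_maps(vol, msk, neighborhood_spec(8, 1), "ri")
  b <- compute_texture_maps(rvol, rmsk, neighborhood_spec(8, 1), "ri")
  expect_equal(sort(a$values$lbp), sort(b$values$lbp))
})

test_that("slice_axis controls the analysis plane", {
  v <- random_masked_volume(c(10, 12, 14), margin = 3, seed = 404)
  tm1 <- compute_texture_maps(v$volume, v$mask, neighborhood_spec(8, 1),
                              "ri", slice_axis = 1)
  vol_p <- aperm(v$volume, c(2, 3, 1))
  msk_p <- aperm(v$mask, c(2, 3, 1))
  tm3 <- compute_texture_maps(vol_p, msk_p, neighborhood_spec(8, 1),
                              "ri", slice_axis = 3)
  expect_equal(sort(tm1$values$lbp), sort(tm3$values$lbp))
  expect_equal(sort(tm1$values$contrast), sort(tm3$values$contrast))
})
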