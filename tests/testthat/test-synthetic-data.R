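test_that("volume generation is deterministic per seed and distinct across seeds", {
  p <- list(mean = 100, sigma = 10, corr_len = 2)
  a <- generate_volume(p, c(24, 24, 6), seed = 1)
  b <- generate_volume(p, c(24, 24, 6), seed = 1)
  c <- generate_volume(p, c(24, 24, 6), seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$volume, c$volume))
})

test_that("ground-truth masks nest: wml inside wm inside brain", {
  p <- list(mean = 100, sigma = 8, corr_len = 1, n_lesions = 3,
            lesion_radius = c(2, 3), lesion_contrast = 2)
  v <- generate_volume(p, c(32, 32, 8), seed = 3)
  expect_true(all(v$wml_truth <= v$wm_mask))
  expect_true(all(v$wm_mask <= v$brain_mask))
  expect_gt(sum(v$wml_truth), 0)
})

test_that("the marginal SD of the texture matches the requested sigma within 5%", {
  for (ell in c(1, 3)) {
    v <- generate_volume(list(mean = 0, sigma = 10, corr_len = ell),
                         c(64, 64, 12), seed = 4)
    inside <- v$volume[v$brain_mask > 0]
    expect_gt(length(inside), 1e4)
    expect_lt(abs(sd(inside) - 10) / 10, 0.05)
  }
})

test_that("sigma = 0 gives a constant brain and all-zero contrast features", {
  v <- generate_volume(list(mean = 100, sigma = 0, corr_len = 2),
                       c(24, 24, 6), seed = 5)
  expect_equal(sd(v$volume[v$brain_mask > 0]), 0)
  fv <- extract_features(v$volume, v$wm_mask, specs = default_specs()[1])
  expect_true(all(unlist(fv[grepl("^C_", names(fv))]) == 0))
})

test_that("correlation length separates riu2 miscellaneous-code frequencies between classes", {
  freq9 <- function(ell, seed) {
    v <- generate_volume(list(mean = 100, sigma = 10, corr_len = ell),
                         c(32, 32, 6), seed = seed)
    tm <- compute_texture_maps(v$volume, v$wm_mask, neighborhood_spec(8, 1),
                               "riu2")
    mean(tm$values$lbp == 9)
  }
  rough <- sapply(1:20, function(s) freq9(1, 1000 + s))
  smooth <- sapply(1:20, function(s) freq9(4, 2000 + s))
  # smoother fields produce fewer non-uniform patterns
  expect_gt(median(rough), median(smooth))
  w <- stats::wilcox.test(rough, smooth, alternative = "greater")
  expect_lt(w$p.value, 1e-3)
})

test_that("cohort generation writes volumes, masks and a subject table, reproducibly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- synthetic_cohort_spec(
    list(A = list(n = 2, mean = 100, sigma = 5, corr_len = 1),
         B = list(n = 2, mean = 100, sigma = 5, corr_len = 3)),
    volume_shape = c(16, 16, 4), seed = 9)
  m1 <- generate_cohort(spec, dir1)
  m2 <- generate_cohort(spec, dir2)
  expect_equal(nrow(m1), 4)
  expect_true(all(file.exists(m1$volume)))
  expect_true(file.exists(file.path(dir1, "subjects.csv")))
  expect_equal(read_volume(m1$volume[1]), read_volume(m2$volume[1]),
               ignore_attr = TRUE)
  expect_equal(m1$label, c("A", "A", "B", "B"))
})

test_that("profiles encode the intended designs", {
  s <- cohort_profile("paper-imbalance")
  expect_equal(sapply(s$classes, `[[`, "n"), c(NC = 36, AD = 57, LBD = 16))
  null <- cohort_profile("null")
  expect_equal(length(unique(sapply(null$classes, `[[`, "corr_len"))), 1)
  sig <- cohort_profile("signal-2class")
  cls <- sapply(sig$classes, `[[`, "corr_len")
  expect_equal(unname(max(cls) / min(cls)), 4)
})
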