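#' Specification of a synthetic MRI-like cohort
#'
#' Describes a cohort of 3D volumes with class-dependent stationary texture:
#' each subject's volume is a class mean intensity plus a Gaussian random
#' field obtained by in-plane Gaussian smoothing (kernel SD = the
#' correlation length `corr_len`, in voxels) of white noise, rescaled to a
#' marginal SD `sigma`. The in-plane correlation length is the class signal
#' the texture operators must detect: smoother fields produce fewer
#' non-uniform local binary patterns. Optional hyperintense spherical
#' lesions (intensity = `lesion_contrast` x class mean, recorded in a ground
#' truth mask) support segmentation tests.
#'
#' @param classes Named list, one element per class, each a list with fields
#'   `n` (subject count), `mean` (mean intensity), `sigma` (marginal SD),
#'   `corr_len` (in-plane correlation length, voxels), and optionally
#'   `n_lesions`, `lesion_radius` (range, voxels), `lesion_contrast` (> 1).
#' @param volume_shape Integer triple, default `c(48, 48, 8)`.
#' @param seed Integer seed; every volume derives its own stream from it.
#'
#' @return An object of class `synthetic_cohort_spec`.
#' @examples
#' cohort_profile("balanced")
#' @export
synthetic_cohort_spec <- function(classes, volume_shape = c(48, 48, 8), seed = 1) {
  stopifnot(is.list(classes), length(classes) >= 1, !is.null(names(classes)))
  for (cl in names(classes)) {
    p <- classes[[cl]]
    if (p$n < 0) abort("Class counts must be >= 0.")
    if (p$corr_len <= 0) abort("`corr_len` must be > 0.")
    if (p$sigma < 0) abort("`sigma` must be >= 0.")
    if (!is.null(p$lesion_contrast) && p$lesion_contrast <= 1)
      abort("`lesion_contrast` must be > 1.")
  }
  structure(list(classes = classes, volume_shape = as.integer(volume_shape),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Ready-made cohort profiles
#'
#' * `"paper-imbalance"`: three classes NC/AD/LBD with counts 36/57/16 —
#'   the imbalance profile of a typical dementia cohort (57 AD, 16 LBD,
#'   36 controls) — and correlation lengths 1, 2 and 4 voxels.
#' * `"balanced"`: the same three texture classes at 30 subjects each.
#' * `"null"`: three classes with identical texture parameters (no signal),
#'   30 subjects each.
#' * `"signal-2class"`: two classes whose correlation lengths differ by a
#'   factor of 4 (1 vs 4 voxels), 30 subjects each.
#'
#' @param profile Profile name.
#' @param seed Integer seed.
#' @param volume_shape Integer triple, default `c(48, 48, 8)`.
#' @return A [synthetic_cohort_spec()].
#' @examples
#' cohort_profile("null", seed = 7)
#' @export
cohort_profile <- function(profile = c("paper-imbalance", "balanced", "null",
                                       "signal-2class"),
                           seed = 1, volume_shape = c(48, 48, 8)) {
  profile <- match.arg(profile)
  base <- function(n, corr_len) list(n = n, mean = 100, sigma = 10,
                                     corr_len = corr_len)
  classes <- switch(profile,
    "paper-imbalance" = list(NC = base(36, 1), AD = base(57, 2),
                             LBD = base(16, 4)),
    "balanced" = list(NC = base(30, 1), AD = base(30, 2), LBD = base(30, 4)),
    "null" = list(NC = base(30, 2), AD = base(30, 2), LBD = base(30, 2)),
    "signal-2class" = list(A = base(30, 1), B = base(30, 4)))
  synthetic_cohort_spec(classes, volume_shape = volume_shape, seed = seed)
}

#' Generate one synthetic brain-like volume
#'
#' Builds an ellipsoidal brain mask with a concentric white-matter-like
#' subregion, fills the brain with `mean` plus a Gaussian random field
#' (in-plane Gaussian smoothing of white noise, kernel SD `corr_len`,
#' rescaled to marginal SD `sigma`), and optionally inserts hyperintense
#' spherical lesions inside the WM region at intensity
#' `lesion_contrast * mean` (plus the local field), recorded in a ground
#' truth lesion mask.
#'
#' @param params List with `mean`, `sigma`, `corr_len` and optionally
#'   `n_lesions`, `lesion_radius` (length-2 range), `lesion_contrast`.
#' @param shape Integer triple of volume dimensions.
#' @param seed Integer seed; the result is deterministic per seed.
#'
#' @return A list with `volume`, `brain_mask`, `wm_mask`, `wml_truth`
#'   (3D arrays of identical dimensions; masks are 0/1 with
#'   `wml_truth <= wm_mask <= brain_mask`).
#' @examples
#' v <- generate_volume(list(mean = 100, sigma = 10, corr_len = 2),
#'                      shape = c(32, 32, 6), seed = 1)
#' range(v$volume[v$brain_mask > 0])
#' @export
generate_volume <- function(params, shape = c(48, 48, 8), seed = 1) {
  set.seed(seed)
  d <- as.integer(shape)
  brain <- ellipsoid_mask(d, semi = d / 2 - 1)
  wm <- ellipsoid_mask(d, semi = 0.62 * (d / 2 - 1))

  field <- array(rnorm(prod(d)), d)
  if (params$corr_len > 0.2) field <- smooth_in_plane(field, params$corr_len)
  s <- sd(field[brain > 0]) # calibrate the marginal SD where it matters
  if (params$sigma > 0 && s > 0) field <- field * (params$sigma / s)
  else field <- field * 0

  vol <- array(0, d)
  vol[brain > 0] <- params$mean + field[brain > 0]

  wml <- array(0L, d)
  n_les <- params$n_lesions %||% 0
  if (n_les > 0) {
    rr <- params$lesion_radius %||% c(2, 4)
    contrast <- params$lesion_contrast %||% 2
    centers <- which(wm > 0, arr.ind = TRUE)
    if (nrow(centers) < 10) abort("WM region too small for lesions.")
    for (l in seq_len(n_les)) {
      ctr <- centers[sample.int(nrow(centers), 1), ]
      rad <- runif(1, rr[1], rr[2])
      sph <- sphere_voxels(d, ctr, rad)
      sph <- sph & wm > 0
      wml[sph] <- 1L
      vol[sph] <- contrast * params$mean + field[sph]
    }
  }
  list(volume = vol, brain_mask = brain, wm_mask = wm, wml_truth = wml)
}

ellipsoid_mask <- function(d, semi) {
  ctr <- (d + 1) / 2
  i <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  j <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  k <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(i, j, `+`), k, `+`)
  array(as.integer(r2 <= 1), d)
}

sphere_voxels <- function(d, ctr, rad) {
  i <- (seq_len(d[1]) - ctr[1])^2
  j <- (seq_len(d[2]) - ctr[2])^2
  k <- (seq_len(d[3]) - ctr[3])^2
  outer(outer(i, j, `+`), k, `+`) <= rad^2
}

# Separable Gaussian smoothing within each slice (axes 1 and 2); kernel SD
# = ell voxels, truncated at 3 SD, renormalized at the borders.
smooth_in_plane <- function(a, ell) {
  d <- dim(a)
  K1 <- gauss_matrix(d[1], ell)
  K2 <- gauss_matrix(d[2], ell)
  for (s in seq_len(d[3])) a[, , s] <- K1 %*% a[, , s] %*% t(K2)
  a
}

gauss_matrix <- function(n, ell) {
  half <- ceiling(3 * ell)
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(abs(i - j) <= half,
                                   exp(-(i - j)^2 / (2 * ell^2)), 0))
  K / rowSums(K)
}

#' Generate a cohort of synthetic volumes on disk
#'
#' Writes one NIfTI volume plus brain/WM/lesion-truth masks per subject and
#' a subject CSV (`subject_id`, `label`, file paths). Deterministic per the
#' spec's seed: subject `s` uses seed `spec$seed * 10000 + s`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param dir Output directory (created if missing).
#' @return A tibble manifest: `subject_id`, `label`, `volume`, `brain_mask`,
#'   `wm_mask`, `wml_truth` (paths). Also written to `dir/subjects.csv`.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); s <- 0L
  for (cl in names(spec$classes)) {
    p <- spec$classes[[cl]]
    for (r in seq_len(p$n)) {
      s <- s + 1L
      id <- sprintf("sub-%03d", s)
      v <- generate_volume(p, spec$volume_shape, seed = spec$seed * 10000L + s)
      paths <- file.path(dir, paste0(id, "_", c("vol", "brain", "wm", "wml"), ".nii.gz"))
      ok <- tryCatch({
        write_volume(v$volume, paths[1]); write_volume(v$brain_mask, paths[2])
        write_volume(v$wm_mask, paths[3]); write_volume(v$wml_truth, paths[4])
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok))
        abort(sprintf("Failed writing volumes for subject %s: %s", id,
                      conditionMessage(ok)))
      rows[[s]] <- tibble(subject_id = id, label = cl, volume = paths[1],
                          brain_mask = paths[2], wm_mask = paths[3],
                          wml_truth = paths[4])
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "subjects.csv"), row.names = FALSE)
  manifest
}

#' Simulate a cohort and extract its feature table in memory
#'
#' Convenience wrapper: generates each subject's volume, extracts the
#' 48-feature texture vector inside the WM mask, and returns the cohort
#' table ready for [run_nested_cv()]. No files are written.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param variant LBP variant, `"ri"` (default) or `"riu2"`.
#' @param specs Neighbourhood geometries (default [default_specs()]).
#' @return A tibble: `subject_id`, `label`, then 48 feature columns.
#' @export
simulate_cohort_features <- function(spec, variant = "ri", specs = default_specs()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  rows <- list(); s <- 0L
  for (cl in names(spec$classes)) {
    p <- spec$classes[[cl]]
    for (r in seq_len(p$n)) {
      s <- s + 1L
      v <- generate_volume(p, spec$volume_shape, seed = spec$seed * 10000L + s)
      fv <- extract_features(v$volume, v$wm_mask, specs = specs,
                             variant = variant,
                             subject_id = sprintf("sub-%03d", s),
                             modality = "synthetic", roi = "WM")
      fv$label <- cl
      rows[[s]] <- fv
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "subject_id", "label",
                dplyr::all_of(feature_names(specs)))
}
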