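#' Configuration for slice-wise WML threshold segmentation
#'
#' White-matter hyperintensities are segmented from a FLAIR-like volume by
#' thresholding each slice at `scale_factor` times the mode of the slice's
#' brain-intensity histogram. The scale factor has no universal value — it
#' depends on acquisition — so it is a required argument with no default;
#' calibrate it on synthetic volumes (see [generate_volume()]) or on data
#' with known lesions.
#'
#' @param scale_factor Positive multiplier of the slice-histogram mode.
#' @param histogram_bins Number of equal-width histogram bins used for the
#'   mode estimate (default 256).
#' @param min_brain_voxels_per_slice Slices with fewer brain voxels than this
#'   yield no mode estimate and no lesions (default 50).
#'
#' @return An object of class `wml_config`.
#' @examples
#' wml_config(scale_factor = 1.4)
#' @export
wml_config <- function(scale_factor, histogram_bins = 256,
                       min_brain_voxels_per_slice = 50) {
  if (missing(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0)
    abort("`scale_factor` is required and must be a single positive number.")
  if (histogram_bins < 2) abort("`histogram_bins` must be at least 2.")
  structure(list(scale_factor = scale_factor,
                 histogram_bins = as.integer(histogram_bins),
                 min_brain_voxels_per_slice = as.integer(min_brain_voxels_per_slice)),
            class = "wml_config")
}

#' Histogram mode of slice intensities
#'
#' Centre of the most populated bin of a fixed-bin histogram spanning
#' `[min, max]` of the values. Ties are broken toward the lower bin. If all
#' values are equal the common value is returned.
#'
#' @param intensities Numeric vector of brain-voxel intensities on one slice.
#' @param bins Number of equal-width bins.
#' @return The mode estimate (a single number).
#' @examples
#' slice_mode(c(rep(50, 10), rep(200, 2)), bins = 2) # 87.5
#' @export
slice_mode <- function(intensities, bins = 256) {
  if (length(intensities) == 0L) abort("No intensities supplied.")
  lo <- min(intensities); hi <- max(intensities)
  if (hi == lo) return(lo)
  width <- (hi - lo) / bins
  bin <- pmin(floor((intensities - lo) / width) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  b <- which.max(counts) # which.max takes the first (lowest) maximal bin
  lo + (b - 0.5) * width
}

#' Segment white-matter hyperintensities by slice-wise mode thresholding
#'
#' For each slice along `slice_axis`, brain voxels whose intensity strictly
#' exceeds `scale_factor` times the slice's histogram mode are labelled as
#' white-matter lesion. Slices with too few brain voxels produce no lesions.
#' The output mask is always a subset of `brain_mask`, and the threshold
#' scales with the mode, so multiplying the volume by a positive constant
#' leaves the segmentation unchanged.
#'
#' @param flair_volume 3D numeric array (FLAIR-like contrast: lesions
#'   hyperintense).
#' @param brain_mask 3D array of the same dimensions; > 0 marks brain.
#' @param config A [wml_config()].
#' @param slice_axis Axis indexing slices (default 3).
#'
#' @return A 3D integer array (0/1) of the same dimensions: the WML mask.
#' @examples
#' vol <- array(100, c(16, 16, 4)); vol[6:8, 6:8, 2] <- 220
#' brain <- array(1, dim(vol))
#' wml <- segment_wml(vol, brain, wml_config(1.4))
#' sum(wml) # 9
#' @export
segment_wml <- function(flair_volume, brain_mask, config, slice_axis = 3) {
  stopifnot(inherits(config, "wml_config"))
  if (!identical(dim(flair_volume), dim(brain_mask)))
    abort("`flair_volume` and `brain_mask` must have identical dimensions.")
  if (!any(brain_mask > 0)) abort("`brain_mask` is empty.")
  out <- array(0L, dim(flair_volume))
  n_slices <- dim(flair_volume)[slice_axis]
  for (s in seq_len(n_slices)) {
    sl <- slice_extract(flair_volume, slice_axis, s)
    mk <- slice_extract(brain_mask, slice_axis, s) > 0
    vals <- sl[mk]
    if (length(vals) < config$min_brain_voxels_per_slice) next
    thr <- config$scale_factor * slice_mode(vals, config$histogram_bins)
    hit <- mk & sl > thr
    out <- slice_assign(out, slice_axis, s, hit)
  }
  out
}

slice_assign <- function(a, axis, s, sl) {
  sl <- array(as.integer(sl), dim(sl))
  switch(axis,
         { a[s, , ] <- sl; a },
         { a[, s, ] <- sl; a },
         { a[, , s] <- sl; a })
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks. If both masks
#' are empty the overlap is defined as 1.
#'
#' @param a,b Arrays of identical dimensions; > 0 marks foreground.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice_overlap(array(1, c(2, 2, 2)), array(1, c(2, 2, 2))) # 1
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Mask dimensions differ.")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
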