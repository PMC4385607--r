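#' Eight summary statistics of a value distribution
#'
#' Reduces a collection of ROI-wise texture values (LBP codes or contrast
#' values) to the eight statistics used as per-subject features: mean,
#' standard deviation (divisor n-1), variance (= SD squared), median,
#' interquartile range (linear-interpolation quantiles), Shannon entropy in
#' bits, skewness and excess kurtosis (both adjusted Fisher-Pearson, e1071
#' type 2; a normal sample gives values near 0).
#'
#' Entropy for `kind = "discrete_codes"` is taken over the empirical label
#' distribution; for `kind = "continuous"` over a 32-bin histogram spanning
#' `[min, max]`. A constant sample is degenerate: entropy, skewness and
#' kurtosis are all defined as 0.
#'
#' @param values Numeric vector with at least 8 elements (below that,
#'   skewness and kurtosis are too unstable to report).
#' @param kind `"discrete_codes"` for integer label collections (LBP codes)
#'   or `"continuous"` for real-valued collections (contrast).
#' @param context Optional string (e.g. subject/ROI) used in error messages.
#'
#' @return A one-row tibble with columns `mean`, `sd`, `variance`, `median`,
#'   `iqr`, `entropy`, `skewness`, `kurtosis`.
#' @examples
#' summarize_distribution(c(0, 0, 0, 0, 1, 1, 1, 1), "discrete_codes")
#' @export
summarize_distribution <- function(values, kind = c("discrete_codes", "continuous"),
                                   context = NULL) {
  kind <- match.arg(kind)
  if (length(values) < 8)
    abort(paste0("Need at least 8 values to summarize",
                 if (!is.null(context)) paste0(" (", context, ")"), "."))
  s <- sd(values)
  constant <- max(values) - min(values) == 0
  tibble(
    mean = mean(values),
    sd = s,
    variance = s^2,
    median = median(values),
    iqr = unname(quantile(values, 0.75) - quantile(values, 0.25)),
    entropy = if (constant) 0 else shannon_entropy(values, kind),
    skewness = if (constant) 0 else e1071::skewness(values, type = 2),
    kurtosis = if (constant) 0 else e1071::kurtosis(values, type = 2)
  )
}

shannon_entropy <- function(values, kind) {
  p <- if (kind == "discrete_codes") {
    tabulate(match(values, unique(values)))
  } else {
    lo <- min(values); hi <- max(values)
    bin <- pmin(floor((values - lo) / (hi - lo) * 32) + 1L, 32L)
    tabulate(bin, nbins = 32L)
  }
  p <- p[p > 0] / length(values)
  -sum(p * log2(p))
}

#' Names of the 48 texture features, in canonical order
#'
#' Feature order is fixed: for each neighbourhood spec in the given order,
#' the 8 LBP statistics then the 8 contrast statistics. Names look like
#' `LBP_P8_R1_mean` and `C_P16_R4_kurtosis`.
#'
#' @param specs List of [neighborhood_spec()] objects (default the three
#'   standard geometries).
#' @return Character vector of `16 * length(specs)` names.
#' @examples
#' head(feature_names())
#' @export
feature_names <- function(specs = default_specs()) {
  stats <- c("mean", "sd", "variance", "median", "iqr", "entropy",
             "skewness", "kurtosis")
  unlist(lapply(specs, function(sp) {
    tag <- sprintf("P%d_R%g", sp$P, sp$R)
    c(paste("LBP", tag, stats, sep = "_"), paste("C", tag, stats, sep = "_"))
  }), use.names = FALSE)
}

#' Extract the 48-feature texture vector of one subject
#'
#' Computes texture maps for each neighbourhood spec inside the ROI, pools
#' the per-voxel LBP codes (across all slices) and contrast values into one
#' distribution each, and summarizes both with [summarize_distribution()].
#' With the default three geometries this yields 2 descriptors x 3 specs x 8
#' statistics = 48 named features.
#'
#' @param volume 3D numeric array.
#' @param mask 3D ROI mask (> 0 inside), same dimensions.
#' @param specs List of [neighborhood_spec()]s (default [default_specs()]).
#' @param variant `"ri"` or `"riu2"` LBP codes.
#' @param slice_axis Axis indexing 2D slices (default 3).
#' @param subject_id,modality,roi Metadata carried into the output row.
#'
#' @return A one-row tibble: `subject_id`, `modality`, `roi`, then the
#'   feature columns in [feature_names()] order.
#' @examples
#' vol <- array(rnorm(24 * 24 * 4, 100, 5), c(24, 24, 4))
#' msk <- array(0, dim(vol)); msk[6:19, 6:19, ] <- 1
#' extract_features(vol, msk, specs = default_specs()[1],
#'                  subject_id = "s1")
#' @export
extract_features <- function(volume, mask, specs = default_specs(),
                             variant = c("ri", "riu2"), slice_axis = 3,
                             subject_id = NA_character_,
                             modality = NA_character_, roi = NA_character_) {
  variant <- match.arg(variant)
  vals <- lapply(specs, function(sp) {
    tm <- compute_texture_maps(volume, mask, sp, variant, slice_axis)
    if (nrow(tm$values) < 8)
      abort(sprintf("Fewer than 8 mapped voxels for P=%d, R=%g (subject %s).",
                    sp$P, sp$R, subject_id))
    ctx <- sprintf("subject %s, P=%d R=%g", subject_id, sp$P, sp$R)
    con <- summarize_distribution(tm$values$contrast, "continuous", ctx)
    names(con) <- paste0("c_", names(con))
    dplyr::bind_cols(
      summarize_distribution(tm$values$lbp, "discrete_codes", ctx), con)
  })
  row <- dplyr::bind_cols(vals, .name_repair = "minimal")
  names(row) <- feature_names(specs)
  dplyr::bind_cols(tibble(subject_id = subject_id, modality = modality, roi = roi),
                   row)
}
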