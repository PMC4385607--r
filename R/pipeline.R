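#' Run the full texture-classification pipeline on a subject manifest
#'
#' Executes, per subject: optional WML segmentation of the FLAIR-like
#' volume (when no ROI mask is given but a `wml_config` is), texture-feature
#' extraction inside the ROI, then cohort-level nested cross-validation with
#' wrapper feature selection. Artifacts — the 48-feature CSV, per-fold
#' confusion matrices, the m(s) summary table and a machine-readable
#' provenance record (configuration, seed, input checksums) — are written to
#' `out_dir`.
#'
#' @param manifest Data frame with columns `subject_id`, `label`, `volume`
#'   and either `roi_mask` (path to the ROI to analyse) or `brain_mask`
#'   (brain mask from which WML are segmented using `segmentation`).
#' @param out_dir Output directory.
#' @param config A [nested_cv_config()].
#' @param segmentation Optional [wml_config()]; required when `roi_mask` is
#'   absent.
#' @param specs,variant,slice_axis Passed to [extract_features()].
#' @param smote SMOTE placement, see [run_nested_cv()].
#' @param modality Free-text modality tag stored with the features.
#'
#' @return A list with `features` (the cohort tibble) and `cv`
#'   (the [run_nested_cv()] report), invisibly mirrored on disk.
#' @export
run_pipeline <- function(manifest, out_dir, config = nested_cv_config(),
                         segmentation = NULL, specs = default_specs(),
                         variant = "ri", slice_axis = 3,
                         smote = "within-folds", modality = "unknown") {
  manifest <- as_tibble(manifest)
  need <- c("subject_id", "label", "volume")
  if (!all(need %in% names(manifest)))
    abort(sprintf("Manifest must have columns: %s.", paste(need, collapse = ", ")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[r]
    step <- "load"
    res <- tryCatch({
      vol <- read_volume(manifest$volume[r])
      if (!is.null(manifest$roi_mask) && !is.na(manifest$roi_mask[r])) {
        roi <- read_mask(manifest$roi_mask[r])
        roi_tag <- "roi"
      } else {
        if (is.null(segmentation))
          abort("No `roi_mask` column and no `segmentation` config given.")
        step <- "segment"
        brain <- read_mask(manifest$brain_mask[r])
        if (!identical(dim(brain), dim(vol)))
          abort("Mask voxel grid does not match the volume.")
        roi <- segment_wml(vol, brain, segmentation, slice_axis)
        roi_tag <- "wml"
      }
      if (!identical(dim(roi), dim(vol)))
        abort("Mask voxel grid does not match the volume.")
      step <- "extract"
      fv <- extract_features(vol, roi, specs = specs, variant = variant,
                             slice_axis = slice_axis, subject_id = id,
                             modality = modality, roi = roi_tag)
      fv$label <- manifest$label[r]
      fv
    }, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed for subject %s: %s",
                    step, id, conditionMessage(e)))
    })
    rows[[r]] <- res
  }
  features <- dplyr::bind_rows(rows)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  cv <- run_nested_cv(dplyr::select(features, -"subject_id", -"modality", -"roi"),
                      config = config, smote = smote)
  utils::write.csv(cv$folds, file.path(out_dir, "per_fold_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  conf_txt <- file.path(out_dir, "confusions.txt")
  writeLines(unlist(lapply(seq_along(cv$confusions), function(f) {
    c(sprintf("# fold %d", f), utils::capture.output(print(cv$confusions[[f]])), "")
  })), conf_txt)

  prov <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config), smote = smote, variant = variant,
    slice_axis = slice_axis,
    segmentation = if (!is.null(segmentation)) unclass(segmentation),
    inputs = stats::setNames(as.list(unname(tools::md5sum(manifest$volume))),
                             manifest$subject_id))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(features = features, cv = cv))
}
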