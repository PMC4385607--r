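#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file as a plain 3D numeric array, keeping voxel
#' dimensions and the affine as attributes so the grid can be written back
#' unchanged.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A 3D array with attributes `pixdim` and `affine`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("Cannot read NIfTI file %s: %s",
                                                    path, conditionMessage(e))))
  if (length(dim(img)) != 3L)
    abort(sprintf("Expected a 3D volume, got %dD: %s", length(dim(img)), path))
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' Write a 3D array as NIfTI
#'
#' @param volume 3D numeric array; an `affine` attribute (as set by
#'   [read_volume()]) is honoured if present.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  aff <- attr(volume, "affine")
  if (!is.null(aff)) img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask volume
#'
#' Like [read_volume()], but coerces to 0/1: any value greater than 0
#' becomes 1. If values outside `{0, 1}` are present a warning reports the
#' coercion.
#'
#' @param path Path to a NIfTI mask.
#' @return A 3D integer 0/1 array.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    warn(sprintf("Mask %s has values outside {0,1}; coercing > 0 to 1.", path))
  out <- array(as.integer(v > 0), dim(v))
  attributes(out)$pixdim <- attr(v, "pixdim")
  attributes(out)$affine <- attr(v, "affine")
  out
}
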