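#' Construct an in-memory diffusion volume
#'
#' A `GradientVolume` bundles a 4D diffusion-weighted intensity array
#' (indexed `x, y, z, q`) with its voxel spacing, voxel-to-world affine and
#' the gradient table (`bvals`, `bvecs`). It is the container every other
#' layer of the package consumes.
#'
#' @param data 4D numeric array, dimensions `nx x ny x nz x q`.
#' @param spacing numeric length-3, millimetres per voxel (all positive).
#' @param affine 4x4 voxel-to-world matrix (RAS+ mm, 0-based voxel indices).
#'   Defaults to a diagonal affine built from `spacing`.
#' @param bvals numeric length-`q` b-values in s/mm^2.
#' @param bvecs 3 x `q` matrix of unit gradient directions; columns with
#'   `b = 0` may be the zero vector.
#' @return An object of class `GradientVolume`.
#' @export
gradient_volume <- function(data, spacing, affine = NULL, bvals, bvecs) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, q)")
  q <- dim(data)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != q || ncol(bvecs) != q || nrow(bvecs) != 3L)
    stop(sprintf("gradient table mismatch: image has %d frames, %d bvals, %d bvec columns",
                 q, length(bvals), ncol(bvecs)))
  if (any(spacing <= 0)) stop("spacing entries must be strictly positive")
  norms <- sqrt(colSums(bvecs^2))
  bad <- which(bvals > 0 & abs(norms - 1) > 1e-3)
  if (length(bad))
    stop(sprintf("bvec %d has norm %.4f (unit vector required for b > 0)",
                 bad[1], norms[bad[1]]))
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine,
                 bvals = bvals, bvecs = bvecs),
            class = "GradientVolume")
}

#' Construct a 3D scalar volume
#'
#' Shares the spacing/affine conventions of [gradient_volume()]; used for b0
#' images, FA maps and masks.
#'
#' @param data 3D numeric array.
#' @inheritParams gradient_volume
#' @return An object of class `ScalarVolume`.
#' @export
scalar_volume <- function(data, spacing, affine = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(spacing <= 0)) stop("spacing entries must be strictly positive")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "ScalarVolume")
}

#' @export
print.GradientVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("GradientVolume %d x %d x %d, %d frames (%d b=0), spacing %s mm\n",
              d[1], d[2], d[3], d[4], sum(x$bvals <= 50),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.ScalarVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ScalarVolume %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

# plain numeric array without RNifti's internal-image attributes
strip_nifti_attrs <- function(arr) {
  array(as.numeric(arr), dim(arr))
}

#' Read a diffusion volume with its FSL-dialect gradient table
#'
#' Reads a 4D NIfTI image plus `.bval` (one whitespace-separated row) and
#' `.bvec` (three rows) files and validates them against each other: the
#' frame count must match the gradient table and every direction with
#' `b > 0` must be unit length to within `1e-3`.
#'
#' @param image_path path to a 4D NIfTI (`.nii` / `.nii.gz`).
#' @param bval_path,bvec_path paths to the FSL-dialect gradient table.
#' @return A [gradient_volume()].
#' @export
read_gradient_volume <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  arr <- strip_nifti_attrs(as.array(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("%s is not a 4D image", image_path))
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- readLines(bvec_path)
  bvec_rows <- bvec_rows[nzchar(trimws(bvec_rows))]
  if (length(bvec_rows) != 3L)
    stop(sprintf("%s: expected 3 rows, found %d", bvec_path, length(bvec_rows)))
  bvecs <- do.call(rbind, lapply(bvec_rows, function(l) scan(text = l, quiet = TRUE)))
  gradient_volume(data = arr,
                  spacing = RNifti::pixdim(img)[seq_len(3)],
                  affine = unclass(RNifti::xform(img)),
                  bvals = bvals, bvecs = bvecs)
}

#' Read a 3D NIfTI volume
#'
#' @param image_path path to a 3D NIfTI file.
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(image_path) {
  img <- RNifti::readNifti(image_path)
  arr <- strip_nifti_attrs(as.array(img))
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s is not a 3D image", image_path))
  scalar_volume(arr, spacing = RNifti::pixdim(img)[seq_len(3)],
                affine = unclass(RNifti::xform(img)))
}

#' Average the non-diffusion-weighted frames of a volume
#'
#' Returns the mean over all frames whose b-value falls at or below
#' `b0_threshold`; vendors often store b=0 as a small nonzero value, hence
#' the default of 50 s/mm^2. Averaging (rather than taking the first frame)
#' reduces noise in the registration target.
#'
#' @param gv a [gradient_volume()].
#' @param b0_threshold maximum b-value treated as b=0 (s/mm^2).
#' @return A [scalar_volume()] with the same spacing and affine.
#' @export
extract_b0 <- function(gv, b0_threshold = 50) {
  stopifnot(inherits(gv, "GradientVolume"))
  idx <- which(gv$bvals <= b0_threshold)
  if (!length(idx))
    stop(sprintf("no frame with b <= %g s/mm^2; supply a b0 frame or raise b0_threshold",
                 b0_threshold))
  scalar_volume(rowMeans(gv$data[, , , idx, drop = FALSE], dims = 3),
                spacing = gv$spacing, affine = gv$affine)
}

#' Write a volume to NIfTI (plus gradient table for 4D volumes)
#'
#' `GradientVolume` inputs also write `<path minus extensions>.bval` /
#' `.bvec` next to the image so that [read_gradient_volume()] round-trips.
#'
#' @param vol a `GradientVolume`, `ScalarVolume` or `MaskVolume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  if (inherits(vol, "MaskVolume")) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- if (length(dim(data)) == 4L) c(vol$spacing, 1) else vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(data)) "auto" else "float")
  if (inherits(vol, "GradientVolume")) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    writeLines(paste(format(vol$bvals, trim = TRUE), collapse = " "),
               paste0(stem, ".bval"))
    writeLines(apply(vol$bvecs, 1, function(r)
      paste(format(r, trim = TRUE, digits = 17), collapse = " ")),
      paste0(stem, ".bvec"))
  }
  invisible(path)
}
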