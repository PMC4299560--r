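#' CT volume container
#'
#' A 3-D grid of CT attenuation values in Hounsfield units (HU) with voxel
#' spacing. Arrays are stored with \code{dim = c(row, col, slice)}, 1-based,
#' slice 1 being the most superior; \code{x$voxels[, , k]} is axial slice k.
#' HU values are clamped below at \eqn{-1024} (the CT air floor) and stored
#' as integers, following the DICOM convention.
#'
#' @param voxels numeric 3-D array of attenuation values (HU).
#' @param spacing_mm numeric length-3, voxel spacing (row, col, slice) in mm.
#'   The slice entry is the inter-slice spacing (table increment), which for
#'   gapped HRCT protocols exceeds the reconstructed slice thickness.
#' @param slice_thickness_mm reconstructed slice thickness in mm (metadata).
#' @param series_uid identifier written to / checked in series files.
#' @return an object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1),
                      slice_thickness_mm = spacing_mm[3],
                      series_uid = "ctild-series") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_ctild("ctild_validation_error", "`voxels` must be a 3-D array")
  if (any(dim(voxels) < 1L))
    stop_ctild("ctild_validation_error", "volume grid must be non-empty")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_ctild("ctild_validation_error",
               "`spacing_mm` must be 3 positive numbers")
  v <- round(voxels)
  v[v < -1024] <- -1024L
  storage.mode(v) <- "integer"
  structure(
    list(voxels = v, spacing_mm = as.numeric(spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         series_uid = as.character(series_uid)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU in [%d, %d]\n",
              d[1], d[2], d[3], paste(x$spacing_mm, collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Voxel volume of a CT grid in millilitres
#' @param volume a \code{\link{ct_volume}}.
#' @return volume of one voxel in ml.
#' @export
voxel_volume_ml <- function(volume) prod(volume$spacing_mm) / 1000

#' Binary lung mask aligned to a CT volume
#'
#' @param mask logical 3-D array, same shape as the source volume.
#' @param provenance free-form list recording how the mask was produced
#'   (parameters, exclusions); kept so results are auditable.
#' @return an object of class \code{lung_mask} with fields \code{mask},
#'   \code{n_voxels}, \code{provenance}.
#' @export
lung_mask <- function(mask, provenance = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_ctild("ctild_validation_error", "`mask` must be a 3-D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask))
    stop_ctild("ctild_validation_error", "mask must not contain NA")
  structure(list(mask = mask, n_voxels = sum(mask), provenance = provenance),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<lung_mask> %d x %d x %d grid, %d voxels set (%.1f%%)\n",
              d[1], d[2], d[3], x$n_voxels,
              100 * x$n_voxels / length(x$mask)))
  invisible(x)
}

#' @export
dim.lung_mask <- function(x) dim(x$mask)

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    stop_ctild("ctild_validation_error",
               "mask shape (%s) does not match volume shape (%s)",
               paste(dim(mask$mask), collapse = "x"),
               paste(dim(volume$voxels), collapse = "x"))
  invisible(TRUE)
}

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks. Used to
#' compare a computed segmentation against phantom ground truth.
#'
#' @param a,b \code{lung_mask} objects or logical arrays of equal shape.
#' @return Dice coefficient in \code{[0, 1]} (\code{NaN} if both empty).
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "lung_mask")) a$mask else a
  mb <- if (inherits(b, "lung_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb)))
    stop_ctild("ctild_validation_error", "masks have different shapes")
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
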