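#' Parameters for threshold-based lung segmentation
#'
#' @param lung_band inclusive HU interval containing lung parenchyma;
#'   default \code{c(-1024, -200)}, the conventional radiodensity range of
#'   lung isolated from mediastinum and chest wall.
#' @param min_component_voxels connected components smaller than this are
#'   discarded (removes isolated in-band specks).
#' @param connectivity \code{"2d"} labels slices independently with
#'   8-connectivity in-plane (the default, appropriate for gapped 7 mm
#'   protocols where inter-slice connectivity is unreliable) or \code{"3d"}
#'   for 26-connectivity on contiguous volumes.
#' @param closing_radius_vox radius (voxels) of a per-slice morphological
#'   closing applied to the final mask; fills small vessel holes. Default 0
#'   (off): on phantoms with ground truth that excludes vessels, filling
#'   would reintroduce them.
#' @param trachea_policy \code{"top-central"} removes any surviving
#'   component (26-connectivity across slices) that reaches the most
#'   superior slice and whose axial centroid lies in the central third of
#'   the plane in both axes — the trachea/main-bronchi air column;
#'   \code{"none"} disables removal.
#' @return an object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(lung_band = c(-1024, -200),
                                min_component_voxels = 50L,
                                connectivity = c("2d", "3d"),
                                closing_radius_vox = 0,
                                trachea_policy = c("top-central", "none")) {
  connectivity <- match.arg(connectivity)
  trachea_policy <- match.arg(trachea_policy)
  if (length(lung_band) != 2L || lung_band[1] > lung_band[2])
    stop_ctild("ctild_config_error",
               "lung_band lower bound must not exceed upper bound")
  if (!is_count(min_component_voxels) || min_component_voxels < 1)
    stop_ctild("ctild_config_error", "min_component_voxels must be >= 1")
  structure(list(lung_band = as.numeric(lung_band),
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = connectivity,
                 closing_radius_vox = closing_radius_vox,
                 trachea_policy = trachea_policy),
            class = "segmentation_params")
}

#' Semiautomatic lung segmentation by HU thresholding
#'
#' Reproduces the classic density-threshold segmentation used in clinical
#' DICOM viewers: voxels inside \code{lung_band} are candidate lung;
#' connected components touching the axial image border are discarded as
#' exterior air; components below the size filter are dropped; the
#' trachea/large-airway column is removed per \code{trachea_policy}; an
#' optional morphological closing fills small vessel holes. Blood vessels
#' and other soft tissue are excluded implicitly because their attenuation
#' (\eqn{> -200} HU) lies outside the band. Residual non-lung structures
#' can be removed with \code{\link{apply_manual_exclusions}}.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param params a \code{\link{segmentation_params}}.
#' @return a \code{\link{lung_mask}}; its \code{provenance} records the
#'   parameters and the number of trachea components removed.
#' @seealso \code{\link{fibrosis_fraction}} for scoring the result.
#' @export
segment_lungs <- function(volume, params = segmentation_params()) {
  if (!inherits(volume, "ct_volume"))
    stop_ctild("ctild_validation_error", "`volume` must be a ct_volume")
  if (!inherits(params, "segmentation_params"))
    stop_ctild("ctild_validation_error",
               "`params` must be segmentation_params")
  n <- dim(volume$voxels)
  hu <- volume$voxels
  inband <- hu >= params$lung_band[1] & hu <= params$lung_band[2]

  if (!any(inband))
    stop_ctild("ctild_empty_segmentation_error",
               "no voxel in lung band [%g, %g] (size filter %d)",
               params$lung_band[1], params$lung_band[2],
               params$min_component_voxels)

  lab <- .cc_label(inband, n, params$connectivity == "3d")
  ncomp <- attr(lab, "n_components")

  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  border <- logical(ncomp)
  bvox <- c(lab[1, , ], lab[n[1], , ], lab[, 1, ], lab[, n[2], ])
  border[unique(bvox[bvox > 0L])] <- TRUE
  keep <- sizes >= params$min_component_voxels & !border

  mask <- array(FALSE, n)
  mask[lab > 0L] <- keep[lab[lab > 0L]]

  n_trachea <- 0L
  if (params$trachea_policy == "top-central" && any(mask)) {
    # the airway column overlaps slice-to-slice even at 7 mm spacing, so a
    # 3-D pass identifies it regardless of the in-plane connectivity mode
    lab3 <- .cc_label(mask, n, TRUE)
    ncomp3 <- attr(lab3, "n_components")
    top <- unique(lab3[, , 1][lab3[, , 1] > 0L])
    if (length(top)) {
      idx <- which(lab3 > 0L)
      comp <- lab3[idx]
      ai <- arrayInd(idx, n)
      cr <- vapply(split(ai[, 1], comp), mean, numeric(1))
      cc <- vapply(split(ai[, 2], comp), mean, numeric(1))
      ids <- as.integer(names(cr))
      central <- cr > n[1] / 3 & cr < 2 * n[1] / 3 &
                 cc > n[2] / 3 & cc < 2 * n[2] / 3
      drop_ids <- ids[ids %in% top & central]
      if (length(drop_ids)) {
        mask[lab3 %in% drop_ids] <- FALSE
        n_trachea <- length(drop_ids)
      }
    }
  }

  if (params$closing_radius_vox > 0)
    mask <- array(.cc_close(mask, n, params$closing_radius_vox), n)

  if (!any(mask))
    stop_ctild("ctild_empty_segmentation_error",
               "no lung component found in band [%g, %g] (size filter %d)",
               params$lung_band[1], params$lung_band[2],
               params$min_component_voxels)

  lung_mask(mask, provenance = list(params = params,
                                    trachea_components_removed = n_trachea,
                                    manual_exclusions = list()))
}

# Even-odd rule point-in-polygon, vectorized over query points.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Remove manually outlined regions from a lung mask
#'
#' The general mechanism for the "minimal user intervention" of
#' semiautomatic segmentation: per-slice polygons (e.g. around hilar
#' vessels or bronchi the threshold step kept) are subtracted from the
#' mask. Voxels whose centres fall inside a polygon are removed.
#'
#' @param mask a \code{\link{lung_mask}}.
#' @param regions list of regions, each a list with \code{slice} (integer)
#'   and \code{poly}, an n x 2 matrix of (row, col) vertices in 1-based
#'   voxel coordinates.
#' @return a new \code{lung_mask} with the regions removed; \code{n_voxels}
#'   never increases. An empty region list returns the mask unchanged.
#' @export
apply_manual_exclusions <- function(mask, regions = list()) {
  if (!inherits(mask, "lung_mask"))
    stop_ctild("ctild_validation_error", "`mask` must be a lung_mask")
  if (length(regions) == 0L) return(mask)
  n <- dim(mask$mask)
  m <- mask$mask
  for (rg in regions) {
    sl <- rg$slice
    if (!is_count(sl) || sl < 1 || sl > n[3])
      stop_ctild("ctild_bounds_error",
                 "exclusion polygon on nonexistent slice %s", format(sl))
    poly <- rg$poly
    if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
      stop_ctild("ctild_validation_error",
                 "polygon must be an n x 2 matrix with n >= 3")
    if (any(poly[, 1] < 0.5 - 1e-9) || any(poly[, 1] > n[1] + 0.5 + 1e-9) ||
        any(poly[, 2] < 0.5 - 1e-9) || any(poly[, 2] > n[2] + 0.5 + 1e-9))
      stop_ctild("ctild_bounds_error", "polygon vertices outside the grid")
    sel <- which(m[, , sl])
    if (!length(sel)) next
    rc <- arrayInd(sel, n[1:2])
    inside <- point_in_polygon(rc[, 1], rc[, 2], poly[, 1], poly[, 2])
    sl_mat <- m[, , sl]
    sl_mat[sel[inside]] <- FALSE
    m[, , sl] <- sl_mat
  }
  prov <- mask$provenance
  prov$manual_exclusions <- c(prov$manual_exclusions %||% list(), regions)
  lung_mask(m, provenance = prov)
}
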