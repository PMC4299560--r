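#' Specification of a synthetic chest CT phantom
#'
#' Describes a digital phantom emulating a gapped axial HRCT acquisition:
#' two ellipsoidal half-lungs inside a soft-tissue body ellipse, a
#' cylindrical trachea stub entering from the most superior slice, and a few
#' spherical vessel stubs near each hilum. A chosen fraction of lung voxels
#' is assigned fibrotic attenuation; the rest are normal parenchyma.
#'
#' Default attenuation landmarks follow standard chest CT densitometry:
#' air \eqn{-1000} HU, normal lung \eqn{-850} HU (normal parenchyma is
#' conventionally \eqn{-800} to \eqn{-900} HU), fibrotic lung \eqn{-600} HU
#' (inside the abnormal band \eqn{(-700, -200]}), soft tissue \eqn{+40} HU.
#' The default slice geometry mimics a 1.25 mm thickness / 7 mm spacing
#' protocol: slices are sparse axial samples of the thorax.
#'
#' @param grid_shape integer length-3 voxel counts \code{c(rows, cols, slices)}.
#' @param spacing_mm voxel spacing \code{c(row, col, slice)} in mm; the slice
#'   entry is the inter-slice table increment.
#' @param slice_thickness_mm reconstructed slice thickness (metadata only).
#' @param lung_geometry list describing body/lung/trachea/vessel geometry in
#'   voxel units; see \code{\link{default_lung_geometry}}.
#' @param target_fibrotic_fraction fraction in \code{[0, 1]} of lung voxels
#'   assigned fibrotic attenuation.
#' @param hu_params named list of \code{c(mean, sd)} per compartment
#'   (\code{air}, \code{normal_lung}, \code{fibrotic}, \code{soft_tissue}).
#' @param noise_sd additive Gaussian HU noise applied to the whole grid
#'   before integer rounding; default 30 HU, a realistic parenchymal noise
#'   level for low-dose HRCT.
#' @param seed integer RNG seed; identical specs and seeds give
#'   byte-identical phantoms.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 12L),
                         spacing_mm = c(2, 2, 7),
                         slice_thickness_mm = 1.25,
                         lung_geometry = default_lung_geometry(grid_shape),
                         target_fibrotic_fraction = 0.2,
                         hu_params = list(air = c(mean = -1000, sd = 0),
                                          normal_lung = c(mean = -850, sd = 0),
                                          fibrotic = c(mean = -600, sd = 0),
                                          soft_tissue = c(mean = 40, sd = 0)),
                         noise_sd = 30,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop_ctild("ctild_config_error", "grid_shape must be 3 counts >= 4")
  if (!is.numeric(target_fibrotic_fraction) ||
      target_fibrotic_fraction < 0 || target_fibrotic_fraction > 1)
    stop_ctild("ctild_config_error",
               "target_fibrotic_fraction must lie in [0, 1]")
  mu <- vapply(hu_params[c("air", "normal_lung", "fibrotic", "soft_tissue")],
               function(p) unname(p[["mean"]]), numeric(1))
  if (anyNA(mu) || any(diff(mu) <= 0))
    stop_ctild("ctild_config_error",
               "compartment means must be ordered air < normal lung < fibrotic < soft tissue")
  if (noise_sd < 0)
    stop_ctild("ctild_config_error", "noise_sd must be >= 0")
  spec <- structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         slice_thickness_mm = slice_thickness_mm,
         lung_geometry = lung_geometry,
         target_fibrotic_fraction = target_fibrotic_fraction,
         hu_params = hu_params, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
  check_geometry(spec)
  spec
}

#' Default phantom geometry scaled to a grid
#'
#' Positions are relative so the same anatomy fits any grid: a body ellipse
#' filling most of the axial plane, two lung ellipsoids centred at 30% / 70%
#' of the columns (keeping their centroids outside the central third of the
#' plane, where the trachea-removal rule operates), a central trachea
#' cylinder entering at slice 1, and two soft-tissue vessel stubs per lung.
#'
#' @param grid_shape integer length-3 \code{c(rows, cols, slices)}.
#' @return geometry list with elements \code{body}, \code{lungs},
#'   \code{trachea}, \code{vessels}; all coordinates in (possibly
#'   fractional) 1-based voxel units.
#' @export
default_lung_geometry <- function(grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]; ns <- grid_shape[3]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2; cs <- (ns + 1) / 2
  lungs <- list(
    list(center = c(0.52 * nr, 0.30 * nc, cs),
         semi   = c(0.27 * nr, 0.145 * nc, 0.43 * ns)),
    list(center = c(0.52 * nr, 0.70 * nc, cs),
         semi   = c(0.27 * nr, 0.145 * nc, 0.43 * ns)))
  vessels <- list()
  for (lg in lungs) {
    for (dcol in c(-0.05, 0.05) * nc) {
      vessels[[length(vessels) + 1L]] <-
        list(center = c(lg$center[1], lg$center[2] + dcol, cs),
             radius = max(1.6, 0.023 * nc))
    }
  }
  list(
    body = list(center = c(cr, cc), semi = c(0.44 * nr, 0.38 * nc)),
    lungs = lungs,
    trachea = list(center = c(0.40 * nr, cc), radius = 0.045 * nc,
                   slices = c(1L, max(1L, ceiling(0.55 * ns)))),
    vessels = vessels)
}

check_geometry <- function(spec) {
  g <- spec$lung_geometry
  n <- spec$grid_shape
  inside <- function(center, semi) {
    all(center - semi >= 0.5) &&
      all(center + semi <= n[seq_along(center)] + 0.5)
  }
  if (!inside(g$body$center, g$body$semi))
    stop_ctild("ctild_config_error", "body ellipse exceeds the grid")
  for (lg in g$lungs)
    if (!inside(lg$center, lg$semi))
      stop_ctild("ctild_config_error", "lung ellipsoid exceeds the grid")
  tr <- g$trachea
  if (!inside(tr$center, rep(tr$radius, 2)) || tr$slices[2] > n[3])
    stop_ctild("ctild_config_error", "trachea cylinder exceeds the grid")
  invisible(TRUE)
}

# Logical grid of voxels inside an axial ellipse (all slices) or ellipsoid.
ellipse_grid <- function(n, center, semi) {
  r <- slice.index(array(0L, n), 1)
  c <- slice.index(array(0L, n), 2)
  if (length(center) == 2L) {
    ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
  } else {
    s <- slice.index(array(0L, n), 3)
    ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 +
      ((s - center[3]) / semi[3])^2 <= 1
  }
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Builds the compartment label grid from the geometry in \code{spec},
#' assigns the requested number of fibrotic voxels (exactly
#' \code{round(f * n_lung)}, selected with a subpleural preference plus a
#' small seeded jitter, mimicking the peripheral predominance of fibrotic
#' ILD), draws HU values per compartment, adds global Gaussian noise and
#' rounds to integer HU. The ground-truth mask contains exactly the lung
#' parenchyma voxels (normal + fibrotic), excluding trachea and vessels, and
#' the true fibrotic fraction is recorded before noise is added.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return an object of class \code{phantom_volume}: fields \code{volume}
#'   (\code{\link{ct_volume}}), \code{truth_mask} (\code{\link{lung_mask}}),
#'   \code{truth_fibrotic_fraction} (percent), \code{labels} (character
#'   array of compartment labels) and \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(target_fibrotic_fraction = 0.3, seed = 7))
#' ph$truth_fibrotic_fraction
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop_ctild("ctild_config_error", "`spec` must be a phantom_spec")
  check_geometry(spec)
  n <- spec$grid_shape
  g <- spec$lung_geometry

  labels <- array("exterior", n)
  labels[ellipse_grid(n, g$body$center, g$body$semi)] <- "body"

  lung_sel <- array(FALSE, n)
  for (lg in g$lungs) lung_sel <- lung_sel | ellipse_grid(n, lg$center, lg$semi)
  labels[lung_sel] <- "lung_normal"

  tr <- g$trachea
  r <- slice.index(array(0L, n), 1)
  c <- slice.index(array(0L, n), 2)
  s <- slice.index(array(0L, n), 3)
  tr_sel <- (r - tr$center[1])^2 + (c - tr$center[2])^2 <= tr$radius^2 &
    s >= tr$slices[1] & s <= tr$slices[2]
  if (any(tr_sel & lung_sel))
    stop_ctild("ctild_config_error", "trachea overlaps a lung ellipsoid")
  labels[tr_sel] <- "trachea"

  for (v in g$vessels) {
    v_sel <- (r - v$center[1])^2 + (c - v$center[2])^2 +
      (s - v$center[3])^2 <= v$radius^2
    labels[v_sel & lung_sel] <- "vessel"
  }

  lung_idx <- which(labels == "lung_normal")
  n_lung <- length(lung_idx)
  if (n_lung == 0L)
    stop_ctild("ctild_config_error", "geometry yields no lung voxels")
  k <- round(spec$target_fibrotic_fraction * n_lung)

  out <- with_seed(spec$seed, {
    if (k > 0L) {
      # subpleural preference: normalized distance from the nearest lung
      # centre, jittered so the fibrotic region has a ragged edge
      d <- rep(Inf, n_lung)
      for (lg in g$lungs) {
        di <- sqrt(((r[lung_idx] - lg$center[1]) / lg$semi[1])^2 +
                   ((c[lung_idx] - lg$center[2]) / lg$semi[2])^2 +
                   ((s[lung_idx] - lg$center[3]) / lg$semi[3])^2)
        d <- pmin(d, 1 - di)  # small = close to the pleural surface
      }
      score <- d + rnorm(n_lung, 0, 0.15)
      fib <- lung_idx[order(score)[seq_len(k)]]
      labels[fib] <- "lung_fibrotic"
    }

    hp <- spec$hu_params
    # vessels share the soft-tissue compartment; trachea is air
    comp_of <- c(exterior = "air", trachea = "air",
                 lung_normal = "normal_lung", lung_fibrotic = "fibrotic",
                 body = "soft_tissue", vessel = "soft_tissue")
    hu <- array(0, n)
    for (lab in names(comp_of)) {
      who <- labels == lab
      nv <- sum(who)
      if (nv == 0L) next
      p <- hp[[comp_of[[lab]]]]
      m <- unname(p[["mean"]]); sdv <- unname(p[["sd"]])
      hu[who] <- if (sdv > 0) rnorm(nv, m, sdv) else rep(m, nv)
    }

    if (spec$noise_sd > 0)
      hu <- hu + rnorm(length(hu), 0, spec$noise_sd)
    list(hu = hu, labels = labels)
  })

  truth <- out$labels == "lung_normal" | out$labels == "lung_fibrotic"
  structure(
    list(volume = ct_volume(out$hu, spec$spacing_mm, spec$slice_thickness_mm,
                            series_uid = sprintf("ctild-phantom-%d", spec$seed)),
         truth_mask = lung_mask(array(truth, n),
                                provenance = list(source = "phantom",
                                                  seed = spec$seed)),
         truth_fibrotic_fraction = 100 * k / n_lung,
         labels = out$labels,
         spec = spec),
    class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels, %d lung voxels, true FF %.2f%%\n",
              paste(dim(x$volume$voxels), collapse = "x"),
              x$truth_mask$n_voxels, x$truth_fibrotic_fraction))
  invisible(x)
}
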