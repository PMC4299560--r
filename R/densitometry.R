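#' Hounsfield-unit bands for density-mask scoring
#'
#' The fibrosis fraction compares two nested attenuation bands over the
#' segmented lung: the total lung band and the nonfibrotic band. Both start
#' at the CT air floor of \eqn{-1024} HU; the nonfibrotic band ends at the
#' fibrosis threshold (default \eqn{-700} HU), the total band at the
#' parenchyma/soft-tissue boundary (default \eqn{-200} HU). A voxel at
#' exactly the fibrosis threshold counts as nonfibrotic, so the fibrotic
#' band is the half-open interval \eqn{(-700, -200]}.
#'
#' @param total inclusive HU interval of lung parenchyma,
#'   default \code{c(-1024, -200)}.
#' @param nonfibrotic inclusive HU interval of normal (nonfibrotic) lung,
#'   default \code{c(-1024, -700)}; must be nested in \code{total} and
#'   share its lower bound.
#' @return an object of class \code{density_bands}.
#' @export
density_bands <- function(total = c(-1024, -200),
                          nonfibrotic = c(-1024, -700)) {
  if (length(total) != 2L || length(nonfibrotic) != 2L ||
      total[1] > total[2] || nonfibrotic[1] > nonfibrotic[2])
    stop_ctild("ctild_config_error", "bands must be ordered intervals")
  if (nonfibrotic[1] != total[1])
    stop_ctild("ctild_config_error",
               "bands must share the lower bound (CT air floor)")
  if (nonfibrotic[2] > total[2])
    stop_ctild("ctild_config_error",
               "nonfibrotic band must be nested in the total band")
  structure(list(total = as.numeric(total),
                 nonfibrotic = as.numeric(nonfibrotic)),
            class = "density_bands")
}

# population central moments of the masked in-band HU values
hist_moments <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  list(mla = m, m2 = m2,
       skewness = if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) mean(d^4) / m2^2 else NA_real_)
}

#' Density-mask fibrosis fraction and histogram descriptors
#'
#' The pulmonary fibrosis fraction is the percentage of segmented lung
#' volume whose attenuation exceeds the nonfibrotic threshold:
#' \deqn{FF = 100 (N_{total} - N_{nonfibrotic}) / N_{total}}
#' where \eqn{N_{total}} counts masked voxels in the total lung band and
#' \eqn{N_{nonfibrotic}} those in the nonfibrotic band. Equivalently, the
#' volume fraction in the fibrotic band \eqn{(-700, -200]} HU. Histogram
#' descriptors (mean lung attenuation, skewness, Pearson kurtosis with
#' normal = 3) are computed over the \eqn{N_{total}} voxels.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param mask a \code{\link{lung_mask}} aligned to \code{volume}.
#' @param bands a \code{\link{density_bands}}.
#' @return object of class \code{densitometry_result}: fields
#'   \code{fibrosis_fraction_pct}, \code{mla_hu}, \code{skewness},
#'   \code{kurtosis} (both \code{NA} for a constant histogram),
#'   \code{n_total_voxels}, \code{n_nonfibrotic_voxels}, \code{volume_ml}.
#' @examples
#' ph <- generate_phantom(phantom_spec(target_fibrotic_fraction = 0.3,
#'                                     noise_sd = 0, seed = 1))
#' fibrosis_fraction(ph$volume, ph$truth_mask)$fibrosis_fraction_pct
#' @export
fibrosis_fraction <- function(volume, mask, bands = density_bands()) {
  check_aligned(volume, mask)
  if (!inherits(bands, "density_bands"))
    stop_ctild("ctild_validation_error", "`bands` must be density_bands")
  hu <- volume$voxels[mask$mask]
  in_total <- hu >= bands$total[1] & hu <= bands$total[2]
  n_total <- sum(in_total)
  if (n_total == 0L)
    stop_ctild("ctild_undefined_fraction_error",
               "no masked voxel falls in the total band [%g, %g]; the fibrosis fraction is undefined",
               bands$total[1], bands$total[2])
  n_nonfib <- sum(hu >= bands$nonfibrotic[1] & hu <= bands$nonfibrotic[2])
  v <- hu[in_total]
  mo <- hist_moments(v)
  structure(
    list(fibrosis_fraction_pct = 100 * (n_total - n_nonfib) / n_total,
         mla_hu = mo$mla, skewness = mo$skewness, kurtosis = mo$kurtosis,
         n_total_voxels = n_total, n_nonfibrotic_voxels = n_nonfib,
         volume_ml = n_total * voxel_volume_ml(volume),
         bands = bands),
    class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat(sprintf(
    "<densitometry_result> FF %.2f%%  MLA %.1f HU  skew %.3f  kurt %.3f  (%d voxels, %.1f ml)\n",
    x$fibrosis_fraction_pct, x$mla_hu, x$skewness, x$kurtosis,
    x$n_total_voxels, x$volume_ml))
  invisible(x)
}

#' Histogram descriptors of the masked lung attenuation distribution
#'
#' Mean lung attenuation (MLA), skewness \eqn{m_3 / m_2^{3/2}} and Pearson
#' kurtosis \eqn{m_4 / m_2^2} (normal = 3) of the HU histogram over masked
#' voxels inside the total band. For a constant histogram the higher
#' moments are undefined: a \code{ctild_zero_variance_error} is signalled,
#' carrying the (still well-defined) MLA in its \code{mla} field.
#'
#' @inheritParams fibrosis_fraction
#' @param excess if \code{TRUE}, report excess kurtosis (normal = 0).
#' @return list with \code{mla_hu}, \code{skewness}, \code{kurtosis}.
#' @export
histogram_descriptors <- function(volume, mask, bands = density_bands(),
                                  excess = FALSE) {
  check_aligned(volume, mask)
  hu <- volume$voxels[mask$mask]
  v <- hu[hu >= bands$total[1] & hu <= bands$total[2]]
  if (length(v) == 0L)
    stop_ctild("ctild_undefined_fraction_error",
               "no masked voxel falls in the total band")
  mo <- hist_moments(v)
  if (!(mo$m2 > 0))
    stop_ctild("ctild_zero_variance_error",
               "constant HU histogram: skewness/kurtosis undefined (MLA = %g)",
               mo$mla, data = list(mla = mo$mla))
  list(mla_hu = mo$mla, skewness = mo$skewness,
       kurtosis = if (excess) mo$kurtosis - 3 else mo$kurtosis)
}
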