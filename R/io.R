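# Volume input/output.
#
# No DICOM or NIfTI reader is guaranteed in the target environment, so
# volumes travel as a plain-text slice series that preserves the DICOM
# behaviours the pipeline depends on: one file per slice, stored integer
# pixel values mapped to HU by RescaleSlope/RescaleIntercept, slices
# ordered by their recorded position (never by file name), and a series
# UID that must be coherent across a directory.

SERIES_MAGIC <- "# ctild-slice 1"

#' Write a CT volume as a plain-text slice series
#'
#' One file per axial slice. Stored values are \code{(HU - intercept) /
#' slope}, rounded to integer, mimicking the DICOM rescale convention
#' (default intercept \eqn{-1024}, slope 1, so stored values are
#' non-negative for in-range HU).
#'
#' @param volume a \code{\link{ct_volume}} (or a \code{\link{lung_mask}},
#'   written as 0/1 with slope 1 / intercept 0).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param rescale_slope,rescale_intercept rescale tags to write.
#' @return invisibly, the vector of file paths written.
#' @export
write_ct_series <- function(volume, dir, prefix = "slice",
                            rescale_slope = 1, rescale_intercept = -1024) {
  if (inherits(volume, "lung_mask"))
    volume <- ct_volume(volume$mask + 0L, c(1, 1, 1),
                        series_uid = "ctild-mask")
  if (!inherits(volume, "ct_volume"))
    stop_ctild("ctild_validation_error", "`volume` must be a ct_volume")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$voxels)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    # slice 1 is most superior; positions decrease inferiorly
    pos <- -(k - 1) * volume$spacing_mm[3]
    stored <- round((volume$voxels[, , k] - rescale_intercept) / rescale_slope)
    path <- file.path(dir, sprintf("%s_%03d.txt", prefix, k))
    hdr <- c(SERIES_MAGIC,
             paste("# series_uid:", volume$series_uid),
             paste("# slice_position_mm:", format(pos, digits = 12)),
             paste("# pixel_spacing_mm:", volume$spacing_mm[1],
                   volume$spacing_mm[2]),
             paste("# slice_spacing_mm:", volume$spacing_mm[3]),
             paste("# slice_thickness_mm:", volume$slice_thickness_mm),
             paste("# rescale_slope:", rescale_slope),
             paste("# rescale_intercept:", rescale_intercept),
             paste("# rows:", d[1]),
             paste("# cols:", d[2]))
    body <- apply(stored, 1, paste, collapse = " ")
    writeLines(c(hdr, body), path)
    paths[k] <- path
  }
  invisible(paths)
}

parse_slice_header <- function(lines, path) {
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(tag, required = TRUE) {
    hit <- grep(paste0("^# ", tag, ":"), hdr, value = TRUE)
    if (!length(hit)) {
      if (required)
        stop_ctild("ctild_io_error",
                   "missing required tag '%s' in %s", tag, path)
      return(NULL)
    }
    sub(paste0("^# ", tag, ":\\s*"), "", hit[1])
  }
  list(series_uid = get("series_uid"),
       position = as.numeric(get("slice_position_mm")),
       pixel_spacing = as.numeric(strsplit(get("pixel_spacing_mm"), "\\s+")[[1]]),
       slice_spacing = as.numeric(get("slice_spacing_mm")),
       slice_thickness = as.numeric(get("slice_thickness_mm", FALSE) %||% NA),
       slope = as.numeric(get("rescale_slope")),
       intercept = as.numeric(get("rescale_intercept")),
       rows = as.integer(get("rows")), cols = as.integer(get("cols")))
}

#' Read a CT volume from a plain-text slice series
#'
#' Reads every series file in \code{dir}, checks that all slices carry the
#' same series UID (a directory with two series is rejected), applies the
#' rescale slope/intercept of each slice to recover HU, and stacks slices
#' sorted by their recorded position, most superior first — file names play
#' no role in ordering. Missing rescale tags raise an error naming the tag.
#'
#' @param dir directory containing one coherent series.
#' @return a \code{\link{ct_volume}}.
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  keep <- vapply(files, function(f)
    identical(readLines(f, n = 1L), SERIES_MAGIC), logical(1))
  files <- files[keep]
  if (!length(files))
    stop_ctild("ctild_io_error", "no series slices found in %s", dir)
  slices <- lapply(files, function(path) {
    lines <- readLines(path)
    h <- parse_slice_header(lines, path)
    body <- lines[!startsWith(lines, "# ")]
    vals <- scan(text = body, what = numeric(), quiet = TRUE)
    if (length(vals) != h$rows * h$cols)
      stop_ctild("ctild_io_error", "slice %s has %d values, expected %d",
                 path, length(vals), h$rows * h$cols)
    m <- matrix(vals, nrow = h$rows, ncol = h$cols, byrow = TRUE)
    list(header = h, hu = m * h$slope + h$intercept)
  })
  uids <- vapply(slices, function(s) s$header$series_uid, character(1))
  if (length(unique(uids)) != 1L)
    stop_ctild("ctild_io_error",
               "directory %s mixes series UIDs: %s", dir,
               paste(unique(uids), collapse = ", "))
  dims <- vapply(slices, function(s) c(s$header$rows, s$header$cols),
                 integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_ctild("ctild_io_error", "slices disagree on grid shape")
  ord <- order(vapply(slices, function(s) s$header$position, numeric(1)),
               decreasing = TRUE)
  slices <- slices[ord]
  h1 <- slices[[1]]$header
  vox <- array(0, c(h1$rows, h1$cols, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  ct_volume(vox,
            spacing_mm = c(h1$pixel_spacing, h1$slice_spacing),
            slice_thickness_mm = h1$slice_thickness,
            series_uid = h1$series_uid)
}

#' Read a mask written with \code{write_ct_series}
#' @param dir directory containing the mask series.
#' @return a \code{\link{lung_mask}}.
#' @export
read_mask_series <- function(dir) {
  v <- read_ct_series(dir)
  lung_mask(array(v$voxels != 0, dim(v$voxels)),
            provenance = list(source = dir))
}

#' Write / read a cohort table as CSV
#'
#' The CSV header is the documented column set of
#' \code{\link{generate_cohort}}.
#'
#' @param cohort a \code{cohort_table} data frame.
#' @param path CSV file path.
#' @return \code{read_cohort_csv} returns a \code{cohort_table}.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  need <- c("id", "subtype", "cam_extent_pct", "warrick_reader1",
            "warrick_reader2", "warrick_mean", "fvc_pct", "fev1_pct",
            "dlco_pct")
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(x)))
    stop_ctild("ctild_io_error", "cohort CSV %s lacks columns: %s", path,
               paste(setdiff(need, names(x)), collapse = ", "))
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Serialize a densitometry result to JSON
#' @param result a \code{densitometry_result}.
#' @param path output file.
#' @export
write_densitometry_json <- function(result, path) {
  out <- result[c("fibrosis_fraction_pct", "mla_hu", "skewness", "kurtosis",
                  "n_total_voxels", "n_nonfibrotic_voxels", "volume_ml")]
  out$bands <- list(total = result$bands$total,
                    nonfibrotic = result$bands$nonfibrotic)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
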