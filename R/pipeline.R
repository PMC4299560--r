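#' Pipeline configuration
#'
#' Assembles and validates the configuration for \code{\link{run_pipeline}}.
#' All defaults match the published analysis parameters: density bands
#' \eqn{-1024 / -700 / -200} HU and Warrick dichotomization cutoff 7.
#'
#' @param input either \code{list(type = "phantom", spec = phantom_spec())}
#'   or \code{list(type = "series", path = <dir>)}.
#' @param output_dir directory for all stage outputs (created).
#' @param segmentation a \code{\link{segmentation_params}}.
#' @param bands a \code{\link{density_bands}}.
#' @param cohort optional: a \code{\link{cohort_spec}}, a cohort CSV path,
#'   or \code{NULL} to skip the statistics stage.
#' @param warrick_cutoff mild/severe dichotomization cutoff for the ROC
#'   stage.
#' @param seed seed forwarded to generators lacking one.
#' @param log_level "info" or "quiet".
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input, output_dir,
                            segmentation = segmentation_params(),
                            bands = density_bands(),
                            cohort = NULL,
                            warrick_cutoff = 7,
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (missing(output_dir) || is.null(output_dir) || !nzchar(output_dir))
    stop_ctild("ctild_config_error", "output_dir is required")
  if (!is.list(input) || is.null(input$type) ||
      !input$type %in% c("phantom", "series"))
    stop_ctild("ctild_config_error",
               "input must be list(type = 'phantom'|'series', ...)")
  if (input$type == "phantom" && !inherits(input$spec, "phantom_spec"))
    stop_ctild("ctild_config_error", "phantom input needs a phantom_spec")
  if (input$type == "series" && !dir.exists(input$path %||% ""))
    stop_ctild("ctild_config_error", "series input path does not exist")
  if (warrick_cutoff < 0)
    stop_ctild("ctild_config_error", "warrick_cutoff must be >= 0")
  if (is.character(cohort) && !file.exists(cohort))
    stop_ctild("ctild_config_error", "cohort CSV %s does not exist", cohort)
  structure(list(input = input, output_dir = output_dir,
                 segmentation = segmentation, bands = bands,
                 cohort = cohort, warrick_cutoff = warrick_cutoff,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet")
    message(sprintf(paste0("[ctild] ", fmt), ...))
}

run_stage <- function(config, name, fun) {
  pipe_log(config, "stage %s", name)
  tryCatch(fun(), error = function(e) {
    stop_ctild("ctild_pipeline_error", "stage '%s' failed: %s",
               name, conditionMessage(e))
  })
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- jsonlite::serializeJSON(unclass(config))
  writeLines(ser, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full quantification pipeline
#'
#' Executes the configured stages in order — acquire (generate a phantom or
#' read a series), segment, quantify, and optionally cohort statistics —
#' writing every report under \code{output_dir} and returning a run
#' manifest with checksums. Identical configuration and seed give
#' byte-identical numeric reports (the manifest's timestamps excepted).
#'
#' Reports written: \code{volume/} (slice series, phantom input only),
#' \code{mask/} (segmentation series), \code{densitometry.json},
#' \code{cohort.csv}, \code{stats.json}, \code{criterion_table.csv},
#' \code{roc_points.csv}, \code{manifest.json}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_ctild("ctild_config_error", "`config` must be a pipeline_config")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artefacts <- list()

  acq <- run_stage(config, "acquire", function() {
    if (config$input$type == "phantom") {
      ph <- generate_phantom(config$input$spec)
      write_ct_series(ph$volume, file.path(out, "volume"))
      list(volume = ph$volume, truth = ph)
    } else {
      list(volume = read_ct_series(config$input$path), truth = NULL)
    }
  })
  if (config$input$type == "phantom")
    artefacts$volume <- md5_of(list.files(file.path(out, "volume"),
                                          full.names = TRUE))

  mask <- run_stage(config, "segment", function() {
    m <- segment_lungs(acq$volume, config$segmentation)
    write_ct_series(m, file.path(out, "mask"), prefix = "mask")
    m
  })
  artefacts$mask <- md5_of(list.files(file.path(out, "mask"),
                                      full.names = TRUE))

  dens <- run_stage(config, "quantify", function() {
    r <- fibrosis_fraction(acq$volume, mask, config$bands)
    write_densitometry_json(r, file.path(out, "densitometry.json"))
    r
  })
  artefacts$densitometry <- md5_of(file.path(out, "densitometry.json"))

  stats_summary <- NULL
  if (!is.null(config$cohort)) {
    stats_summary <- run_stage(config, "statistics", function() {
      coh <- if (is.character(config$cohort)) read_cohort_csv(config$cohort)
      else generate_cohort(config$cohort)
      write_cohort_csv(coh, file.path(out, "cohort.csv"))
      s <- cohort_statistics(coh, warrick_cutoff = config$warrick_cutoff)
      write.csv(s$criterion_table, file.path(out, "criterion_table.csv"),
                row.names = FALSE)
      write.csv(s$roc$points, file.path(out, "roc_points.csv"),
                row.names = FALSE)
      jsonlite::write_json(s$summary, file.path(out, "stats.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      s
    })
    artefacts$statistics <- md5_of(file.path(
      out, c("cohort.csv", "criterion_table.csv", "roc_points.csv",
             "stats.json")))
  }

  manifest <- list(
    software = paste("ctild", as.character(packageVersion("ctild"))),
    config_hash = config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    truth = if (!is.null(acq$truth))
      list(fibrotic_fraction_pct = acq$truth$truth_fibrotic_fraction),
    results = list(
      fibrosis_fraction_pct = dens$fibrosis_fraction_pct,
      mla_hu = dens$mla_hu,
      mask_voxels = mask$n_voxels),
    stages = artefacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cohort-level statistical battery
#'
#' The validation statistics for a cohort table: Pearson correlation and
#' regression of CaM extent against the consensus Warrick score and each
#' PFT, inter-reader ICC(2,1), subtype comparisons (pooled t for CaM,
#' chi-square for the severity dichotomy), and ROC analysis of CaM extent
#' against severe fibrosis (consensus Warrick above the cutoff) with the
#' full criterion table and Youden-optimal threshold.
#'
#' @param cohort a \code{cohort_table}.
#' @param warrick_cutoff severe-fibrosis cutoff on the consensus score.
#' @return list with \code{summary} (flat list of headline numbers),
#'   \code{correlations}, \code{roc}, \code{criterion_table}.
#' @export
cohort_statistics <- function(cohort, warrick_cutoff = 7) {
  cam <- cohort$cam_extent_pct
  severe <- cohort$warrick_mean > warrick_cutoff
  if (!any(severe) || all(severe))
    stop_ctild("ctild_validation_error",
               "cohort has a single severity class at cutoff %g",
               warrick_cutoff)
  cors <- list(
    warrick = pearson_regression(cam, cohort$warrick_mean),
    fvc = pearson_regression(cam, cohort$fvc_pct),
    fev1 = pearson_regression(cam, cohort$fev1_pct),
    dlco = pearson_regression(cam, cohort$dlco_pct))
  icc <- icc_two_way(cbind(cohort$warrick_reader1, cohort$warrick_reader2))
  roc <- roc_analysis(cam, severe)
  ct <- criterion_table(roc)
  tt <- compare_groups(cam[cohort$subtype == "dcSSc"],
                       cam[cohort$subtype == "lcSSc"], kind = "t_test")
  chi <- compare_groups(table(cohort$subtype, severe), kind = "chi_square")
  opt <- roc$points[roc$points$criterion == roc$optimal_threshold, ]
  list(
    summary = list(
      n = nrow(cohort),
      r_cam_warrick = cors$warrick$r, p_cam_warrick = cors$warrick$p_value,
      r_cam_fvc = cors$fvc$r, r_cam_fev1 = cors$fev1$r,
      r_cam_dlco = cors$dlco$r,
      reader_icc = icc,
      auc = roc$auc, auc_se = roc$auc_se,
      optimal_threshold = roc$optimal_threshold,
      sensitivity_at_optimum_pct = 100 * opt$sensitivity,
      specificity_at_optimum_pct = 100 * opt$specificity,
      t_subtype_cam = tt$statistic, p_subtype_cam = tt$p_value,
      chi_square_subtype_severity = chi$statistic,
      warrick_cutoff = warrick_cutoff),
    correlations = cors, reader_icc = icc, roc = roc,
    criterion_table = ct)
}
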