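#' @rdname severity_points
#' @format NULL
#' @export
warrick_abnormalities <- c(ground_glass = 1L,
                           irregular_pleural_margins = 2L,
                           septal_subpleural_lines = 3L,
                           honeycombing = 4L,
                           subpleural_cysts = 5L)

#' Warrick severity point values
#'
#' The Warrick HRCT scoring system assigns a fixed point value to each of
#' five abnormality patterns: ground-glass appearance 1, irregular pleural
#' margins 2, septal/subpleural lines 3, honeycombing 4, subpleural cysts 5.
#' \code{warrick_abnormalities} is the named point table.
#'
#' @param abnormality character vector of abnormality names (see
#'   \code{names(warrick_abnormalities)}).
#' @return integer point values.
#' @export
severity_points <- function(abnormality) {
  bad <- setdiff(abnormality, names(warrick_abnormalities))
  if (length(bad))
    stop_ctild("ctild_validation_error",
               "unknown abnormality: %s (expected one of %s)",
               paste(bad, collapse = ", "),
               paste(names(warrick_abnormalities), collapse = ", "))
  unname(warrick_abnormalities[abnormality])
}

#' Warrick extent grade from an involved-segment count
#'
#' Grades the anatomical extent of one abnormality by the number of
#' bronchopulmonary segments involved: 0 segments grade 0, 1-3 grade 1,
#' 4-9 grade 2, more than 9 grade 3.
#'
#' @param n_segments non-negative integer vector of involved segments.
#'   Counts above 18 (the standard bronchopulmonary segment count) trigger
#'   a warning but are graded (grade 3).
#' @return integer grades in 0-3.
#' @export
extent_grade <- function(n_segments) {
  if (!is.numeric(n_segments) || anyNA(n_segments) ||
      any(n_segments < 0) || any(n_segments != floor(n_segments)))
    stop_ctild("ctild_validation_error",
               "segment counts must be non-negative integers")
  if (any(n_segments > 18))
    warning("segment count above 18, the standard bronchopulmonary segment count")
  as.integer(cut(n_segments, breaks = c(-0.5, 0.5, 3.5, 9.5, Inf),
                 labels = FALSE)) - 1L
}

#' Build a Warrick case from per-abnormality segment counts
#'
#' @param findings named numeric vector or list mapping abnormality names
#'   to involved-segment counts; missing abnormalities count as absent.
#' @return object of class \code{warrick_case}: a full named integer vector
#'   over the five abnormalities.
#' @export
warrick_case <- function(findings = c()) {
  x <- unlist(findings)
  if (length(x)) {
    bad <- setdiff(names(x), names(warrick_abnormalities))
    if (is.null(names(x)) || length(bad))
      stop_ctild("ctild_validation_error",
                 "findings must be named by the five Warrick abnormalities%s",
                 if (length(bad)) paste0(" (unknown: ",
                                         paste(bad, collapse = ", "), ")")
                 else "")
    if (anyNA(x) || any(x < 0) || any(x != floor(x)))
      stop_ctild("ctild_validation_error",
                 "segment counts must be non-negative integers")
  }
  full <- setNames(integer(5), names(warrick_abnormalities))
  full[names(x)] <- as.integer(x)
  structure(full, class = "warrick_case")
}

#' Score a Warrick case
#'
#' Severity is the sum of point values over abnormalities present in at
#' least one segment (1 + 2 + 3 + 4 + 5 = 15 at most); extent is the sum of
#' per-abnormality extent grades (at most 3 each, 15 in all); the total
#' HRCT score is their sum, 0-30. Cases are dichotomized at a cutoff
#' (default 7) into mild (total <= cutoff) and severe (total > cutoff)
#' lung fibrosis.
#'
#' @param case a \code{\link{warrick_case}} (or something coercible).
#' @param cutoff dichotomization cutoff, default 7.
#' @return object of class \code{warrick_score}: \code{severity},
#'   \code{extent}, \code{total}, \code{category} ("mild"/"severe").
#' @examples
#' score_case(warrick_case(c(ground_glass = 2, honeycombing = 10)))
#' @export
score_case <- function(case, cutoff = 7) {
  if (!inherits(case, "warrick_case")) case <- warrick_case(case)
  present <- unclass(case) > 0L
  severity <- sum(warrick_abnormalities[present])
  extent <- sum(extent_grade(unclass(case)))
  total <- severity + extent
  structure(list(severity = as.integer(severity),
                 extent = as.integer(extent),
                 total = as.integer(total),
                 category = if (total > cutoff) "severe" else "mild",
                 cutoff = cutoff),
            class = "warrick_score")
}

#' @export
print.warrick_score <- function(x, ...) {
  cat(sprintf("<warrick_score> severity %d + extent %d = total %d (%s, cutoff %g)\n",
              x$severity, x$extent, x$total, x$category, x$cutoff))
  invisible(x)
}

#' Consensus of two independent readers
#'
#' Element-wise arithmetic mean of two equal-length vectors of per-patient
#' total scores; half points are permitted. The mean of two independent
#' readers is the conventional reference standard for semiquantitative
#' HRCT scoring.
#'
#' @param scores_reader1,scores_reader2 numeric vectors of the same length.
#' @return numeric vector of per-patient mean scores.
#' @export
reader_consensus <- function(scores_reader1, scores_reader2) {
  if (length(scores_reader1) != length(scores_reader2))
    stop_ctild("ctild_validation_error",
               "reader score lists have different lengths (%d vs %d)",
               length(scores_reader1), length(scores_reader2))
  (scores_reader1 + scores_reader2) / 2
}

#' Score a long-format findings table
#'
#' @param findings data frame with columns \code{patient_id},
#'   \code{abnormality}, \code{n_segments} (one row per finding), as read
#'   from a findings CSV.
#' @param cutoff dichotomization cutoff passed to \code{\link{score_case}}.
#' @return data frame with one row per patient: \code{patient_id},
#'   \code{severity}, \code{extent}, \code{total}, \code{category}.
#' @export
score_findings_table <- function(findings, cutoff = 7) {
  need <- c("patient_id", "abnormality", "n_segments")
  if (!all(need %in% names(findings)))
    stop_ctild("ctild_validation_error",
               "findings table needs columns: %s", paste(need, collapse = ", "))
  ids <- unique(findings$patient_id)
  rows <- lapply(ids, function(id) {
    f <- findings[findings$patient_id == id, ]
    cnt <- tapply(f$n_segments, f$abnormality, sum)
    sc <- score_case(warrick_case(cnt), cutoff = cutoff)
    data.frame(patient_id = id, severity = sc$severity, extent = sc$extent,
               total = sc$total, category = sc$category)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
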