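#' Pearson correlation with least-squares regression line
#'
#' Product-moment correlation \eqn{r}, the least-squares line of y on x,
#' and the two-sided p-value from the \eqn{t = r\sqrt{(n-2)/(1-r^2)}}
#' transform with \eqn{n - 2} degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, \eqn{n \ge 3}, finite, with
#'   nonzero variance.
#' @return list with \code{r}, \code{slope}, \code{intercept},
#'   \code{p_value}, \code{t}, \code{df}, \code{n}.
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y))
    stop_ctild("ctild_validation_error", "x and y must have equal length")
  n <- length(x)
  if (n < 3L)
    stop_ctild("ctild_validation_error", "need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_ctild("ctild_validation_error", "values must be finite")
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0)
    stop_ctild("ctild_undefined_correlation_error",
               "zero variance in x or y: correlation undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sx * sy)
  slope <- sxy / sx
  tval <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  list(r = r, slope = slope, intercept = mean(y) - slope * mean(x),
       p_value = 2 * pt(-abs(tval), df = n - 2), t = tval,
       df = n - 2L, n = n)
}

#' Two-way intraclass correlation coefficient
#'
#' ICC from the two-way mean-squares decomposition of an
#' \eqn{n \times k} subjects-by-raters matrix. The default form is
#' ICC(2,1): two-way random effects, absolute agreement, single measure,
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}.}
#' The consistency form ICC(C,1) = \eqn{(MS_R - MS_E)/(MS_R + (k-1) MS_E)}
#' ignores systematic rater offsets and is provided for comparison.
#'
#' @param ratings numeric matrix, one row per subject, one column per
#'   rater; no missing cells, at least 2 raters and 2 subjects.
#' @param type \code{"agreement"} (ICC(2,1), default) or
#'   \code{"consistency"}.
#' @return the ICC value (scalar).
#' @export
icc_two_way <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop_ctild("ctild_validation_error", "ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2L || n < 2L)
    stop_ctild("ctild_validation_error",
               "need at least 2 raters and 2 subjects")
  g <- mean(ratings)
  ri <- rowMeans(ratings); cj <- colMeans(ratings)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  mse <- sum((ratings - outer(ri, rep(1, k)) -
                outer(rep(1, n), cj) + g)^2) / ((n - 1) * (k - 1))
  if (msr <= 0 || (msr == mse && mse == 0))
    stop_ctild("ctild_degenerate_icc_error",
               "no between-subject variance: ICC undefined")
  switch(type,
         agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         consistency = (msr - mse) / (msr + (k - 1) * mse))
}

#' Two-group comparisons: pooled t-test and Pearson chi-square
#'
#' \code{kind = "t_test"}: classical two-sample Student t with pooled
#' variance. \code{kind = "chi_square"}: Pearson's X² without continuity
#' correction, either on a contingency table passed as \code{a} or on the
#' cross-tabulation of two categorical vectors.
#'
#' @param a,b for the t-test, the two numeric samples; for chi-square,
#'   either \code{a} is a contingency matrix (and \code{b} is ignored) or
#'   \code{a}, \code{b} are paired categorical vectors.
#' @param kind \code{"t_test"} or \code{"chi_square"}.
#' @return list with \code{statistic}, \code{p_value}, \code{df}.
#' @export
compare_groups <- function(a, b = NULL, kind = c("t_test", "chi_square")) {
  kind <- match.arg(kind)
  if (kind == "t_test") {
    na <- length(a); nb <- length(b)
    if (na < 2L || nb < 2L)
      stop_ctild("ctild_validation_error", "need n >= 2 per group")
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    if (sp2 == 0) {
      if (mean(a) == mean(b))
        return(list(statistic = 0, p_value = 1, df = na + nb - 2L))
      stop_ctild("ctild_validation_error",
                 "zero pooled variance with unequal means")
    }
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(statistic = tval, p_value = 2 * pt(-abs(tval), df = na + nb - 2),
         df = na + nb - 2L)
  } else {
    tab <- if (is.matrix(a)) a else as.matrix(table(a, b))
    if (any(dim(tab) < 2L))
      stop_ctild("ctild_validation_error",
                 "chi-square needs at least a 2 x 2 table")
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd == 0))
      stop_ctild("ctild_validation_error", "table has an empty margin")
    stat <- sum((tab - expd)^2 / expd)
    df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
         df = df)
  }
}

#' ROC analysis with criterion-level confusion counts
#'
#' Thresholds are the distinct score values plus one value below the
#' minimum; a case is classified positive when its score is strictly above
#' the criterion (the ">c" convention of criterion tables). Sensitivity is
#' the fraction of positives above the criterion, specificity the fraction
#' of negatives at or below it. The AUC is the trapezoidal area under the
#' (FPR, TPR) staircase, which equals the Mann-Whitney pair-counting
#' estimate with ties counted one half; its standard error uses the
#' Hanley-McNeil formula. The optimal threshold maximizes the Youden index
#' (sensitivity + specificity - 1), the smallest criterion on ties.
#'
#' @param scores numeric vector (higher = more diseased).
#' @param labels binary vector (logical, 0/1, or a 2-level factor with the
#'   positive class given by \code{positive}).
#' @param positive value of \code{labels} identifying the positive
#'   (diseased) class; default \code{TRUE}/\code{1}.
#' @return object of class \code{roc_result}: \code{auc}, \code{auc_se},
#'   \code{optimal_threshold}, \code{youden}, \code{n_pos}, \code{n_neg}
#'   and a data frame \code{points} with per-criterion \code{criterion},
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}, \code{sensitivity},
#'   \code{specificity}.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels))
    stop_ctild("ctild_validation_error", "scores and labels differ in length")
  if (any(!is.finite(scores)))
    stop_ctild("ctild_validation_error", "scores must be finite")
  pos <- if (is.null(positive)) {
    if (is.logical(labels)) labels else labels == max(as.numeric(labels))
  } else labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_ctild("ctild_validation_error",
               "both classes must be present for ROC analysis")
  uq <- sort(unique(scores))
  crit <- c(uq[1] - 1, uq)
  tp <- vapply(crit, function(cr) sum(pos & scores > cr), numeric(1))
  fp <- vapply(crit, function(cr) sum(!pos & scores > cr), numeric(1))
  fn <- n_pos - tp
  tn <- n_neg - fp
  sens <- tp / n_pos
  spec <- tn / n_neg
  fpr <- 1 - spec
  # staircase ordered from (1,1) at the lowest criterion to (0,0) at the top
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                    (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  youden <- sens + spec - 1
  opt <- which(youden == max(youden))[1]
  structure(
    list(auc = auc, auc_se = auc_se,
         optimal_threshold = crit[opt], youden = youden[opt],
         n_pos = n_pos, n_neg = n_neg,
         points = data.frame(criterion = crit, tp = tp, fp = fp,
                             tn = tn, fn = fn, sensitivity = sens,
                             specificity = spec)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f), optimal criterion > %.4g (Youden %.3f), %d+/%d-\n",
              x$auc, x$auc_se, x$optimal_threshold, x$youden,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return numeric \code{c(lower, upper)} on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (!is_count(x) || !is_count(n) || x > n || n < 1)
    stop_ctild("ctild_validation_error", "need 0 <= x <= n, n >= 1")
  a <- (1 - conf) / 2
  c(lower = if (x == 0) 0 else qbeta(a, x, n - x + 1),
    upper = if (x == n) 1 else qbeta(1 - a, x + 1, n - x))
}

lr_ci <- function(lr, se_log, conf = 0.95) {
  if (!is.finite(lr) || lr <= 0 || !is.finite(se_log))
    return(c(lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  c(lower = exp(log(lr) - z * se_log), upper = exp(log(lr) + z * se_log))
}

#' MedCalc-style criterion table for a ROC analysis
#'
#' One row per criterion with sensitivity and specificity (exact
#' Clopper-Pearson 95% CIs), positive and negative likelihood ratios
#' (log-method CIs), and predictive values computed transparently from the
#' observed confusion counts (not prevalence-adjusted), with exact CIs.
#' The positive likelihood ratio is omitted (\code{NA}) where specificity
#' is 100%.
#'
#' @param roc a \code{\link{roc_analysis}} result.
#' @param conf confidence level, default 0.95.
#' @return data frame with columns \code{criterion}, \code{sensitivity_pct}
#'   (+ \code{_lo}/\code{_hi}), \code{specificity_pct} (+ CIs),
#'   \code{lr_pos}, \code{lr_neg} (+ CIs), \code{ppv_pct}, \code{npv_pct}
#'   (+ CIs).
#' @export
criterion_table <- function(roc, conf = 0.95) {
  if (!inherits(roc, "roc_result"))
    stop_ctild("ctild_validation_error", "`roc` must be a roc_result")
  p <- roc$points
  rows <- lapply(seq_len(nrow(p)), function(i) {
    tp <- p$tp[i]; fp <- p$fp[i]; tn <- p$tn[i]; fn <- p$fn[i]
    np <- tp + fn; nn <- tn + fp
    sens <- tp / np; spec <- tn / nn
    ci_se <- clopper_pearson(tp, np, conf)
    ci_sp <- clopper_pearson(tn, nn, conf)
    lr_pos <- if (spec == 1) NA_real_ else sens / (1 - spec)
    se_pos <- if (tp > 0 && fp > 0)
      sqrt(1 / tp - 1 / np + 1 / fp - 1 / nn) else NA_real_
    lr_neg <- if (spec == 0) NA_real_ else (1 - sens) / spec
    se_neg <- if (fn > 0 && tn > 0)
      sqrt(1 / fn - 1 / np + 1 / tn - 1 / nn) else NA_real_
    ci_lp <- lr_ci(lr_pos, se_pos, conf)
    ci_ln <- lr_ci(lr_neg, se_neg, conf)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    ci_pp <- if (tp + fp > 0) clopper_pearson(tp, tp + fp, conf) else
      c(NA_real_, NA_real_)
    ci_np <- if (tn + fn > 0) clopper_pearson(tn, tn + fn, conf) else
      c(NA_real_, NA_real_)
    data.frame(criterion = p$criterion[i],
               sensitivity_pct = 100 * sens,
               sensitivity_lo = 100 * ci_se[1], sensitivity_hi = 100 * ci_se[2],
               specificity_pct = 100 * spec,
               specificity_lo = 100 * ci_sp[1], specificity_hi = 100 * ci_sp[2],
               lr_pos = lr_pos, lr_pos_lo = ci_lp[1], lr_pos_hi = ci_lp[2],
               lr_neg = lr_neg, lr_neg_lo = ci_ln[1], lr_neg_hi = ci_ln[2],
               ppv_pct = 100 * ppv, ppv_lo = 100 * ci_pp[1],
               ppv_hi = 100 * ci_pp[2],
               npv_pct = 100 * npv, npv_lo = 100 * ci_np[1],
               npv_hi = 100 * ci_np[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
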