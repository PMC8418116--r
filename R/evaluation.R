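#' Confusion matrix and diagnostic metrics
#'
#' The positivity convention throughout the package is "index <= cutoff means
#' ischemic": a positive case is a hemodynamically significant stenosis.
#'
#' @param tp,tn,fp,fn Non-negative counts (true/false positives/negatives).
#'
#' @return `confusion_matrix()` returns a `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("Counts must be non-negative integers.")
  }
  if (sum(counts) == 0) stop_invalid("At least one observation is required.")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix`.
#' @return `confusion_metrics()` returns a one-row tibble with `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` as unrounded percentages
#'   (`NA` where the denominator is zero — an undefined metric is reported
#'   as missing, never as 0).
#' @export
#'
#' @examples
#' confusion_metrics(confusion_matrix(tp = 53, tn = 125, fp = 21, fn = 3))
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop_invalid("`cm` must be a confusion_matrix.")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  tibble(
    accuracy = pct(cm$tp + cm$tn, total),
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv = pct(cm$tp, cm$tp + cm$fp),
    npv = pct(cm$tn, cm$tn + cm$fn),
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
}

#' Cross-classify an index against a reference standard
#'
#' Both the index and the reference are dichotomised with the "value <=
#' cutoff is positive (ischemic)" convention; values exactly at a cutoff
#' count as positive. The reference default 0.80 is the established FFR
#' ischemia threshold.
#'
#' @param index_values Numeric vector of index values (e.g. SmartFFR).
#' @param reference_values Numeric vector of reference values (e.g. invasive
#'   FFR), same length.
#' @param index_cutoff Positivity cutoff for the index.
#' @param reference_cutoff Positivity cutoff for the reference, default 0.80.
#'
#' @return A [confusion_matrix()].
#' @export
classify <- function(index_values, reference_values, index_cutoff,
                     reference_cutoff = 0.80) {
  if (length(index_values) != length(reference_values)) {
    stop_invalid("`index_values` and `reference_values` must have the same length.")
  }
  test_pos <- index_values <= index_cutoff
  ref_pos <- reference_values <= reference_cutoff
  confusion_matrix(
    tp = sum(test_pos & ref_pos),
    tn = sum(!test_pos & !ref_pos),
    fp = sum(test_pos & !ref_pos),
    fn = sum(!test_pos & ref_pos)
  )
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the argument checks used across
#' the evaluation layer.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-zero variance.
#'
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have the same length.")
  if (length(x) < 3) stop_invalid("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance.", class = "smartffr_undefined_correlation")
  }
  cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `x - y`; the bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * sd` (sample SD, n - 1 denominator). The
#' confidence interval of each limit uses the classical approximation
#' `limit +/- t(0.975, n-1) * sd * sqrt(3/n)`.
#'
#' @param x,y Paired measurements (e.g. SmartFFR and invasive FFR),
#'   equal length, n >= 3.
#'
#' @return A `bland_altman_result` list with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ci_low_limit`, `ci_high_limit`, `n`, and the per-case
#'   `means`/`differences` used for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have the same length.")
  n <- length(x)
  if (n < 3) stop_invalid("Need at least 3 paired observations.")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  half_ci <- qt(0.975, n - 1) * s * sqrt(3 / n)
  structure(
    list(
      bias = bias, sd_diff = s,
      loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      ci_low_limit = c(bias - 1.96 * s - half_ci, bias - 1.96 * s + half_ci),
      ci_high_limit = c(bias + 1.96 * s - half_ci, bias + 1.96 * s + half_ci),
      n = n, means = (x + y) / 2, differences = d
    ),
    class = "bland_altman_result"
  )
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Orientation: a LOW index value indicates disease, so a case is called
#' positive when its value is `<= t`. Candidate thresholds are the sorted
#' unique observed values; the AUC is the trapezoidal integral of the ROC
#' curve, which equals the Mann-Whitney concordance probability (with tie
#' correction) of the negated scores. The optimal cutoff maximises the
#' Youden index `J = sensitivity + specificity - 1`; ties are broken in
#' favour of the largest threshold (the most sensitive of the maximisers).
#'
#' @param index_values Numeric index values.
#' @param disease_labels 0/1 (or logical) disease indicators, both classes
#'   present.
#'
#' @return A `roc_result` list with `auc`, `thresholds`, `sensitivity`,
#'   `specificity`, `youden_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_youden <- function(index_values, disease_labels) {
  lab <- as.integer(disease_labels)
  if (length(index_values) != length(lab)) {
    stop_invalid("Values and labels must have the same length.")
  }
  if (!all(lab %in% c(0L, 1L))) stop_invalid("`disease_labels` must be 0/1.")
  n_pos <- sum(lab == 1L)
  n_neg <- sum(lab == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid("Both diseased and non-diseased cases are required.")
  }
  thresholds <- sort(unique(index_values))
  sens <- vapply(thresholds, function(t) sum(index_values <= t & lab == 1L) / n_pos, 0)
  spec <- vapply(thresholds, function(t) sum(index_values > t & lab == 0L) / n_neg, 0)
  j <- sens + spec - 1
  best <- max(which(j == max(j))) # tie-break: largest maximising threshold
  # Mann-Whitney AUC on negated scores via midranks (tie-corrected)
  r <- rank(index_values)
  auc <- (n_pos * n_neg + n_pos * (n_pos + 1) / 2 - sum(r[lab == 1L])) / (n_pos * n_neg)
  structure(
    list(auc = auc, thresholds = thresholds, sensitivity = sens,
         specificity = spec, youden_cutoff = thresholds[best],
         youden_j = j[best], n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' DeLong comparison of two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two markers measured on the same
#' cases, via DeLong's placement-value (structural-component) estimator of
#' the AUC variance-covariance. Orientation matches [roc_youden()]: low
#' values indicate disease. Identical score vectors give `z = 0`, `p = 1`
#' by convention.
#'
#' @param scores_1,scores_2 Paired marker values on the same cases.
#' @param disease_labels 0/1 disease indicators, both classes present.
#'
#' @return A `delong_result` list with `auc_1`, `auc_2`, `var_1`, `var_2`,
#'   `cov_12`, `se_diff`, `z_statistic`, `p_value`.
#' @export
delong_compare <- function(scores_1, scores_2, disease_labels) {
  lab <- as.integer(disease_labels)
  if (length(scores_1) != length(lab) || length(scores_2) != length(lab)) {
    stop_invalid("Scores and labels must have the same length.")
  }
  if (!all(lab %in% c(0L, 1L)) || sum(lab == 1L) == 0 || sum(lab == 0L) == 0) {
    stop_invalid("`disease_labels` must be 0/1 with both classes present.")
  }
  # negate so that HIGH transformed score = diseased (standard orientation)
  comp <- lapply(list(-scores_1, -scores_2), delong_placements, lab = lab)
  m <- sum(lab == 1L)
  n <- sum(lab == 0L)
  auc <- vapply(comp, `[[`, 0, "auc")
  v10 <- vapply(comp, `[[`, numeric(m), "v10")
  v01 <- vapply(comp, `[[`, numeric(n), "v01")
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  var_auc <- diag(s10) / m + diag(s01) / n
  cov_auc <- s10[1, 2] / m + s01[1, 2] / n
  se_diff <- sqrt(max(0, var_auc[1] + var_auc[2] - 2 * cov_auc))
  if (se_diff == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (auc[1] - auc[2]) / se_diff
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_1 = auc[1], auc_2 = auc[2],
         var_1 = var_auc[1], var_2 = var_auc[2], cov_12 = cov_auc,
         se_diff = se_diff, z_statistic = z, p_value = p),
    class = "delong_result"
  )
}

# Placement values: for diseased case i, V10_i = mean_j psi(x_i, y_j) over
# non-diseased j, with psi = 1, 1/2, 0 for x > y, x == y, x < y; V01_j is the
# mirror image. mean(V10) = mean(V01) = AUC.
delong_placements <- function(scores, lab) {
  x <- scores[lab == 1L]
  y <- scores[lab == 0L]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f; Youden cutoff = %g (J = %.3f); %d diseased / %d non-diseased\n",
              x$auc, x$youden_cutoff, x$youden_j, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> bias = %.4f (SD %.4f); 95%% LoA [%.4f, %.4f]; n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC1 = %.4f vs AUC2 = %.4f; z = %.3f, p = %.4g\n",
              x$auc_1, x$auc_2, x$z_statistic, x$p_value))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d | FP %d | FN %d | TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
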