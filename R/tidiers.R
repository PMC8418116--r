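#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-element table a plot or report would consume, `glance()` a
#' one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#'
#' @return A tibble.
#' @name smartffr-tidiers
NULL

#' @rdname smartffr-tidiers
#' @method tidy smartffr_result
#' @export
tidy.smartffr_result <- function(x, ...) {
  out <- as_tibble(x$curve)
  out$source <- attr(x$curve, "source") %||% NA_character_
  out
}

#' @rdname smartffr-tidiers
#' @method glance smartffr_result
#' @export
glance.smartffr_result <- function(x, ...) {
  tibble(
    vessel_id = x$vessel_id %||% NA_character_,
    branch_id = x$branch_id %||% NA_character_,
    smartffr = x$value, auc = x$auc
  )
}

#' @rdname smartffr-tidiers
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(
    threshold = x$thresholds,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    youden_j = x$sensitivity + x$specificity - 1
  )
}

#' @rdname smartffr-tidiers
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, youden_cutoff = x$youden_cutoff, youden_j = x$youden_j,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname smartffr-tidiers
#' @method tidy bland_altman_result
#' @export
tidy.bland_altman_result <- function(x, ...) {
  tibble(mean = x$means, difference = x$differences)
}

#' @rdname smartffr-tidiers
#' @method glance bland_altman_result
#' @export
glance.bland_altman_result <- function(x, ...) {
  tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_low_limit_lo = x$ci_low_limit[1], ci_low_limit_hi = x$ci_low_limit[2],
    ci_high_limit_lo = x$ci_high_limit[1], ci_high_limit_hi = x$ci_high_limit[2],
    n = x$n
  )
}

#' @rdname smartffr-tidiers
#' @method glance delong_result
#' @export
glance.delong_result <- function(x, ...) {
  tibble(auc_1 = x$auc_1, auc_2 = x$auc_2, se_diff = x$se_diff,
         z_statistic = x$z_statistic, p_value = x$p_value)
}

#' @rdname smartffr-tidiers
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  confusion_metrics(x)
}

#' @rdname smartffr-tidiers
#' @method glance diagnostic_evaluation
#' @export
glance.diagnostic_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n = x$n, pearson_r = x$pearson_r, auc = x$roc$auc,
           index_cutoff = x$index_cutoff,
           bias = x$bland_altman$bias,
           loa_low = x$bland_altman$loa_low, loa_high = x$bland_altman$loa_high),
    x$metrics[, c("accuracy", "sensitivity", "specificity", "ppv", "npv")]
  )
}
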