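#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects: the Pd/Pa
#' curve with its protocol samples, the ROC curve with the Youden-optimal
#' operating point, and the Bland-Altman agreement plot with its limits.
#'
#' @param object A result object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @name smartffr-autoplot
NULL

#' @rdname smartffr-autoplot
#' @method autoplot pdpa_curve
#' @export
autoplot.pdpa_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$flow_mls, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Flow (ml/s)", y = expression(P[d] / P[a]),
                  title = "Pd/Pa versus flow") +
    ggplot2::theme_minimal()
}

#' @rdname smartffr-autoplot
#' @method autoplot smartffr_result
#' @export
autoplot.smartffr_result <- function(object, ...) {
  p <- autoplot(object$curve) +
    ggplot2::geom_area(alpha = 0.15) +
    ggplot2::labs(subtitle = sprintf("SmartFFR = %.3f (AUC %.3f / 4)",
                                     object$value, object$auc))
  if (!is.null(object$samples)) {
    pts <- tibble(flow_mls = object$samples$flow_mls,
                  ratio = object$samples$pd_mmhg / object$samples$pa_mmhg)
    p <- p + ggplot2::geom_point(data = pts, size = 2)
  }
  p
}

#' @rdname smartffr-autoplot
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  best <- df[df$threshold == object$youden_cutoff, ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc),
                  subtitle = sprintf("Youden cutoff <= %g (J = %.2f)",
                                     object$youden_cutoff, object$youden_j)) +
    ggplot2::theme_minimal()
}

#' @rdname smartffr-autoplot
#' @method autoplot bland_altman_result
#' @export
autoplot.bland_altman_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Mean of methods", y = "Difference",
                  title = "Bland-Altman agreement",
                  subtitle = sprintf("bias %.4f, 95%% LoA [%.4f, %.4f]",
                                     object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a cohort's index against its reference FFR
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param reference_cutoff Reference positivity cutoff drawn as a guide.
#'
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, reference_cutoff = 0.80) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$ffr_measured, y = .data$smartffr,
                               colour = .data$area_stenosis)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = reference_cutoff, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Reference FFR (measured)", y = "SmartFFR",
                  colour = "Area\nstenosis") +
    ggplot2::theme_minimal()
}
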