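# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_smooth
#'   labs scale_x_log10 scale_y_log10 theme_minimal autoplot
NULL

#' Plot a replicate CV report (CV vs amount)
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot(object$per_lipid, aes(x = .data$mean_pmol, y = .data$cv)) +
    geom_point(alpha = 0.6) +
    scale_x_log10() +
    labs(x = "mean amount (pmol)", y = "CV (%)",
         title = sprintf("median CV %.2f%%, %.0f%% below %g%%",
                         object$summary$median_cv,
                         100 * object$summary$frac_below,
                         object$summary$threshold)) +
    theme_minimal()
}

#' Plot a spike-series dynamic-range fit
#' @param object A `dynrange_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dynrange_fit
#' @export
autoplot.dynrange_fit <- function(object, ...) {
  g <- glance(object)
  ggplot(object$data, aes(x = .data$pmol, y = .data$sn)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "spiked amount (pmol)", y = "S/N",
         title = sprintf("slope %.2f, LoQ %g pmol, %.2f orders",
                         g$slope, g$loq_pmol, g$range_orders)) +
    theme_minimal()
}

#' Plot a depth profile (layer totals and class curves)
#' @param object A `depth_profile`.
#' @param what `"total"` or `"classes"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, what = c("total", "classes"), ...) {
  what <- match.arg(what)
  if (what == "total") {
    ggplot(object$layer_totals, aes(x = .data$layer, y = .data$mean_total)) +
      geom_line() + geom_point() +
      labs(x = "stripping layer", y = "total lipid (pmol)") +
      theme_minimal()
  } else {
    ggplot(object$class_curves,
           aes(x = .data$layer, y = .data$mean_molpct, colour = .data$class)) +
      geom_line() +
      labs(x = "stripping layer", y = "class mol%") +
      theme_minimal()
  }
}

#' Plot PCA scores
#' @param object A `lipid_pca`.
#' @param colour Optional vector (length = samples) mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lipid_pca
#' @export
autoplot.lipid_pca <- function(object, colour = NULL, ...) {
  d <- object$scores
  if (!is.null(colour)) d$colour <- colour
  p <- ggplot(d, aes(x = .data$PC1, y = .data$PC2)) +
    labs(
      x = sprintf("PC1 (%.1f%%)", object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", object$var_explained[2])
    ) +
    theme_minimal()
  if (is.null(colour)) p + geom_point() else p + geom_point(aes(colour = .data$colour))
}

#' Plot per-resample random-forest accuracies against the null rate
#' @param object An `rf_sex_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rf_sex_fit
#' @export
autoplot.rf_sex_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$resample, y = .data$accuracy)) +
    geom_point() +
    ggplot2::geom_hline(yintercept = object$null_rate, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy) +
    labs(x = "resample", y = "held-out accuracy",
         title = sprintf("%.3f +- %.3f (null %.3f)", object$mean_accuracy,
                         object$sd_accuracy, object$null_rate)) +
    theme_minimal()
}
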