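# ggplot2 visualisations of the result objects.

#' Bland-Altman plot
#'
#' Paired differences (harmonised - original) against pair means, with the
#' mean difference and 95% limits of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cl_bland_altman
#' @export
autoplot.cl_bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = s$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(s$loa_low, s$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Pair mean (CL)", y = "Difference, harmonised - original (CL)",
                  title = sprintf("Bland-Altman: %.2f +/- %.2f CL", s$mean_diff, s$sd_diff)) +
    ggplot2::theme_minimal()
}

#' Marginal-means plot
#'
#' @param object A [marginal_means()] result.
#' @param ... Unused.
#' @return A ggplot of estimates with 95% CIs per factor level.
#' @method autoplot cl_marginal_means
#' @export
autoplot.cl_marginal_means <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                           width = 0.15) +
    ggplot2::labs(x = attr(object, "factor"), y = "Marginal mean CL") +
    ggplot2::theme_minimal()
}

#' Plot the interpolated within-pipeline CI half-width
#'
#' The CI half-width line between the stratum anchors, evaluated over a CL
#' grid, with the clinical cutoffs marked.
#'
#' @param neg,pos `cl_precision` rows (negative / positive stratum).
#' @param cutoffs CL cutoffs to mark (default 12 and 24).
#' @return A ggplot.
#' @export
plot_ci_interpolation <- function(neg, pos, cutoffs = c(12, 24)) {
  grid <- interpolate_ci(neg, pos, seq(0, 100, by = 2))
  marks <- interpolate_ci(neg, pos, cutoffs)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$cl, y = .data$ci_halfwidth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "Centiloid", y = "95% CI half-width (CL)") +
    ggplot2::theme_minimal()
}
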