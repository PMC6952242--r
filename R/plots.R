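#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot agreement against the reference tool
#'
#' Scatter of the tool's measurements against the reference's, with the
#' identity line (dotted) and the ordinary least-squares regression
#' (dashed) — the standard inter-tool consistency display.
#'
#' @param object An `agreement_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot agreement_stats
#' @export
autoplot.agreement_stats <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$reference_mm, y = .data$value_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s (reference), mm", object$reference),
      y = sprintf("%s, mm", object$tool),
      title = sprintf("%s vs %s: mean diff %.2f ± %.2f mm",
                      object$tool, object$reference,
                      object$mean_diff_mm, object$sd_diff_mm)
    )
  if (!object$degenerate) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = "dashed")
  }
  p
}

#' Plot a phantom accuracy/precision summary
#'
#' Mean measured diameter with +/- 1 SD error bars per tool, against the
#' true insert diameter (dotted line), faceted by profile axis.
#'
#' @param object A `phantom_summary` tibble (see [summarize_phantom()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phantom_summary
#' @export
autoplot.phantom_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$size_mm), y = .data$mean_mm,
                               colour = .data$tool)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mm - .data$sd_mm,
                   ymax = .data$mean_mm + .data$sd_mm),
      width = 0.3, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$size_mm), colour = "black",
                        shape = 3) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "true insert diameter, mm",
                  y = "measured diameter, mm", colour = "tool")
}

#' Plot intra-user variability
#'
#' Per-user, per-tool SD of the deviations from each instance's cross-tool
#' mean, as grouped columns.
#'
#' @param object An `intra_user_variability` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot intra_user_variability
#' @export
autoplot.intra_user_variability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$user, y = .data$sd_mm,
                               fill = .data$tool)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "user", y = "SD of difference from cross-tool mean, mm",
                  fill = "tool")
}

#' Plot a caliper intensity profile
#'
#' The sampled profile through an insert with the detected half-contrast
#' threshold (dashed) and the two edge positions (dotted) — a visual check
#' of the automated caliper.
#'
#' @param object A `caliper_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot caliper_result
#' @export
autoplot.caliper_result <- function(object, ...) {
  half <- object$diameter_mm / 2
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$distance_mm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-half, half), linetype = "dotted") +
    ggplot2::labs(x = "distance from centre, mm", y = "intensity",
                  title = sprintf("%s diameter %.2f mm", object$axis_label,
                                  object$diameter_mm))
}
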