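# Plot methods for result objects.

#' Plot the parametric-bootstrap null distribution
#'
#' Histogram of the per-replicate improvement of the best GC tree over the
#' species tree under the null (no conversion), with the observed improvement
#' marked by a dashed line.
#'
#' @param object A `gc_bootstrap` from [parametric_bootstrap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_bootstrap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_lnL)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_delta,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "lnL(best GC tree) - lnL(species tree)", y = "replicates",
      title = sprintf("Parametric bootstrap (N = %d, p = %.3g)",
                      object$n_reps, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Radical/conservative ratio plot across families
#'
#' Scatter of converted-class versus background-class Rr/Rc across gene
#' families; undefined ratios (Rc at the zero floor) are drawn at `cap` as a
#' display convention. The shaded region marks purifying selection
#' (ratio <= 1) and the diagonal marks equal ratios in the two classes.
#'
#' @param results Tibble with columns `family`, `ratio_background`,
#'   `ratio_converted` (NA = undefined).
#' @param cap Display value for undefined ratios.
#' @return A ggplot object.
#' @export
plot_sg_ratios <- function(results, cap = 5) {
  df <- tibble::as_tibble(results)
  df$undefined <- is.na(df$ratio_converted) | is.na(df$ratio_background)
  df$x <- pmin(ifelse(is.na(df$ratio_background), cap, df$ratio_background), cap)
  df$y <- pmin(ifelse(is.na(df$ratio_converted), cap, df$ratio_converted), cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = 1, ymin = -Inf, ymax = 1,
                      fill = "grey85") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$undefined), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "Rc = 0 (capped)") +
    ggplot2::labs(x = "Rr/Rc, background branches",
                  y = "Rr/Rc, converted branches") +
    ggplot2::theme_minimal()
}
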