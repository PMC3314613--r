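# ggplot2 methods for result objects

#' @describeIn hl_cox Observed vs expected events per risk group.
#' @param object An `hl_cox_test`.
#' @param ... Unused.
#' @export
autoplot.hl_cox_test <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                              names_to = "quantity", values_to = "events")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$group), y = .data$events,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "risk group (low to high predicted risk)", y = "events",
      fill = NULL,
      title = sprintf("Calibration at %g years: chi-square = %.2f (df %d), p = %.3g",
                      object$horizon, object$statistic, object$df, object$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn decile_ratio Predicted/observed ratio per risk group with the
#'   perfect-calibration reference line at 1.
#' @param object A `decile_ratio` tibble.
#' @param ... Unused.
#' @export
autoplot.decile_ratio <- function(object, ...) {
  dat <- object[object$group != "overall", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$group, levels = .data$group),
                                    y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "risk group (low to high predicted risk)",
                  y = "predicted / observed risk") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_cox Forest plot of hazard ratios with 95% CIs.
#' @param object A `cox_refit`.
#' @param ... Unused.
#' @export
autoplot.cox_refit <- function(object, ...) {
  hr <- hazard_ratios(object)
  ggplot2::ggplot(hr, ggplot2::aes(x = .data$hr,
                                   y = factor(.data$term, levels = rev(.data$term)))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hr.low, xmax = .data$hr.high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
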