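#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar
#'   facet_wrap labs scale_x_log10 scale_y_log10 autoplot theme_minimal
#'   geom_hline stat_summary position_jitter
NULL

#' @export
autoplot.spectrum_profile <- function(object, ...) {
  df <- object$bins
  intercept <- mean(log10(df$amplitude)) - object$slope * mean(log10(df$freq))
  ggplot(df, aes(x = .data$freq, y = .data$amplitude)) +
    geom_point() +
    geom_line(aes(y = 10^(intercept + object$slope * log10(.data$freq))),
              linetype = "dashed") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "spatial frequency (cycles/image)",
         y = "mean radial amplitude",
         title = sprintf("Amplitude spectrum (slope %.2f)", object$slope)) +
    theme_minimal()
}

#' @export
autoplot.nt_prf_fit <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$mu, y = .data$ve)) +
    scale_x_log10() +
    labs(x = "preferred numerosity", y = "variance explained",
         title = "pRF grid fit") +
    theme_minimal()
  if ("kind" %in% names(df)) {
    p + geom_point(aes(colour = .data$kind), alpha = 0.5)
  } else {
    p + geom_point(alpha = 0.5)
  }
}

#' Per-subject ROI response plot
#'
#' Dots per subject, median crossbar and an SD error bar for every
#' category, faceted by ROI — the standard presentation of ROI-averaged
#' block responses.
#'
#' @param roi_table An [roi_response_table()] result.
#' @param rois Restrict to these ROIs.
#' @return A ggplot object.
#' @export
plot_roi_responses <- function(roi_table, rois = NULL) {
  df <- as_tibble(roi_table)
  if (!is.null(rois)) df <- dplyr::filter(df, .data$roi %in% rois)
  df <- dplyr::filter(df, !is.na(.data$mean_psc))
  ggplot(df, aes(x = .data$category, y = .data$mean_psc)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_point(aes(colour = factor(.data$subject)),
               position = position_jitter(width = 0.1, height = 0),
               alpha = 0.8) +
    stat_summary(fun = stats::median, geom = "crossbar", width = 0.5,
                 linewidth = 0.3) +
    stat_summary(fun.data = function(y) {
      data.frame(ymin = mean(y) - sd(y), ymax = mean(y) + sd(y), y = mean(y))
    }, geom = "errorbar", width = 0.2) +
    facet_wrap(~roi) +
    labs(x = NULL, y = "response (percent signal change)",
         colour = "subject") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.nt_roi_table <- function(object, ...) plot_roi_responses(object, ...)
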