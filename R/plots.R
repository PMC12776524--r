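#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar geom_errorbarh geom_ribbon geom_abline labs facet_wrap
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Training trace of a fitted ReGNN
#'
#' Per-epoch training loss, L2 norm of the regression coefficients, and
#' (when a ground-truth moderator was traced) the correlation between the
#' index and the truth.
#'
#' @param object a fitted `regnn`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.regnn <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot(tr, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' Feature-importance bars of a Shapley report
#'
#' @param object a `shap_report`.
#' @param top_n how many leading features to show (default 20).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shap_report <- function(object, top_n = 20, ...) {
  sm <- head(object$summary, top_n)
  sm$feature <- factor(sm$feature, levels = rev(sm$feature))
  ggplot(sm, aes(x = .data$estimate, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.3) +
    labs(x = if (object$normalized) "normalized mean |attribution|"
         else "mean |attribution|", y = NULL) +
    theme_minimal()
}

#' Matched-cluster distances across thresholds
#'
#' Scatter of the (non-excluded) matched Mahalanobis distances against
#' the subgroup threshold, with the fitted linear trend.
#'
#' @param object a `threshold_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  kept <- dplyr::filter(object$matches, !.data$excluded)
  p <- ggplot(kept, aes(x = .data$threshold, y = .data$distance)) +
    geom_point(alpha = 0.7) +
    labs(x = "index threshold (quantile)", y = "Mahalanobis distance") +
    theme_minimal()
  if (nrow(object$trend)) {
    p <- p + geom_abline(
      intercept = object$trend$estimate[object$trend$term == "(Intercept)"],
      slope = object$trend$estimate[object$trend$term == "threshold"],
      colour = "firebrick"
    )
  }
  p
}

#' Plot a precision-recall curve
#'
#' @param curve a tibble from [precision_recall_curve()].
#' @return a ggplot.
#' @export
plot_precision_recall <- function(curve) {
  ggplot(dplyr::filter(curve, !is.na(.data$precision)),
         aes(x = .data$recall, y = .data$precision)) +
    geom_line() +
    labs(x = "recall", y = "precision") +
    theme_minimal()
}

#' Plot predicted-outcome profiles
#'
#' Predicted outcome against the exposure at the chosen index
#' percentiles, with 95\% confidence ribbons; diverging slopes display
#' the moderation captured by the index.
#'
#' @param profiles a tibble from [predict_profiles()].
#' @return a ggplot.
#' @export
plot_profiles <- function(profiles) {
  profiles$z_level <- factor(profiles$z_level)
  ggplot(profiles, aes(x = .data$xf, y = .data$fit,
                       colour = .data$z_level, fill = .data$z_level)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "exposure", y = "predicted outcome",
         colour = "index percentile", fill = "index percentile") +
    theme_minimal()
}
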