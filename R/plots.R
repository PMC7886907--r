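#' Plot precision-recall and ROC curves
#'
#' @param object An `lce_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lce_eval <- function(object, ...) {
  df <- tidy(object)
  df$curve <- ifelse(df$curve == "pr",
                     sprintf("PR (AUPRC = %.3f)", object$auprc),
                     sprintf("ROC (AUROC = %.3f)", object$auroc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(color = "#2166ac") +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = "recall / FPR", y = "precision / TPR") +
    ggplot2::theme_minimal()
}

#' Plot the calibration metric surface
#'
#' One panel per decay setting, metric against `a`, colored by `w`.
#'
#' @param object An `lce_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lce_fit <- function(object, ...) {
  df <- object$surface
  df$decay_lab <- ifelse(df$decay == "exponential",
                         paste0("exp, lambda = ", df$lam),
                         ifelse(df$decay == "powerlaw",
                                paste0("powerlaw, k = ", df$k), "no decay"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$metric,
                                   color = factor(.data$w),
                                   group = factor(.data$w))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~decay_lab) +
    ggplot2::labs(y = object$metric, color = "w") +
    ggplot2::theme_minimal()
}

#' Heatmap of the predicted contact-ratio map around a perturbed site
#'
#' @param object An `lce_contact_map` from [crossing_outside_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lce_contact_map <- function(object, ...) {
  df <- dplyr::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_i, y = .data$start_j,
                                   fill = log2(.data$ratio))) +
    ggplot2::geom_tile(data = df[df$class == "Gray", ],
                       fill = "grey70") +
    ggplot2::geom_tile(data = df[df$class != "Gray", ]) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::geom_vline(xintercept = attr(object, "target_pos"),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "bin i (bp)", y = "bin j (bp)",
                  fill = "log2 weak/strong") +
    ggplot2::theme_minimal()
}
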