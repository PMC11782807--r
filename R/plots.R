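#' Plot a training history
#'
#' Train and validation loss per epoch, with the best epoch marked.
#'
#' @param object A `cinefuse_history` tibble (from `model$history`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cinefuse_history
#' @export
autoplot.cinefuse_history <- function(object, ...) {
  d <- tidyr::pivot_longer(object,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (target units²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-feature predictive performance
#'
#' Frame-level PCC as a phase-by-view heat map, with summary and final
#' features shown alongside.
#'
#' @param object A `feature_importance` tibble.
#' @param metric Which column to display (default `"pcc"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_importance
#' @export
autoplot.feature_importance <- function(object, metric = "pcc", ...) {
  d <- dplyr::mutate(object,
                     row = dplyr::case_when(
                       .data$level == "frame" ~ .data$view,
                       .data$level == "spatial_summary" ~ "spatial summary",
                       .data$level == "temporal_summary" ~ "temporal summary",
                       TRUE ~ "final"),
                     col = dplyr::case_when(
                       .data$level == "frame" ~ as.numeric(.data$phase),
                       .data$level == "spatial_summary" ~ as.numeric(.data$phase),
                       .data$level == "temporal_summary" ~
                         as.numeric(match(.data$view, unique(.data$view))),
                       TRUE ~ 1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "phase / component", y = NULL, fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot mean attention weights
#'
#' One panel per fusion kind, components on the x axis.
#'
#' @param object An `attention_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attention_summary
#' @export
autoplot.attention_summary <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$component, y = .data$group,
                               fill = .data$mean_weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ .data$fusion, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "component", y = "fusion group", fill = "mean weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a chamber perturbation grid
#'
#' Table-style tile plot of perturbed PCC per mode, view, and chamber.
#'
#' @param object A `perturbation_grid` from [chamber_importance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perturbation_grid
#' @export
autoplot.perturbation_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$chamber, y = .data$view,
                                       fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pcc)),
                       na.rm = TRUE, size = 3) +
    ggplot2::facet_wrap(~ .data$mode) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "chamber", y = NULL,
                  subtitle = sprintf("intact PCC %.2f",
                                     attr(object, "intact_pcc"))) +
    ggplot2::theme_minimal()
}

#' Scatter and Bland-Altman plot of predictions
#'
#' @param truth,pred Equal-length numeric vectors (target units).
#' @param target Axis label for the target.
#' @return A list of two ggplots: `scatter` and `bland_altman`.
#' @export
plot_agreement <- function(truth, pred, target = "target") {
  d <- tibble::tibble(truth = truth, pred = pred,
                      avg = (truth + pred) / 2, diff = pred - truth)
  ba <- bland_altman(truth, pred)
  scatter <- ggplot2::ggplot(d, ggplot2::aes(.data$truth, .data$pred)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = paste("measured", target), y = paste("predicted", target)) +
    ggplot2::theme_minimal()
  bland <- ggplot2::ggplot(d, ggplot2::aes(.data$avg, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_lower, ba$loa_upper),
                        linetype = c(1, 2, 2)) +
    ggplot2::labs(x = paste("mean of measured and predicted", target),
                  y = "prediction - measurement") +
    ggplot2::theme_minimal()
  list(scatter = scatter, bland_altman = bland)
}
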