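#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   facet_wrap labs theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot a fine-tuning trace
#'
#' Three panels against the outer iteration: fine-tuning MSE, training-set
#' misclassification rate, and test-set misclassification rate.
#'
#' @param object An `sae_trace` tibble (from [gd_finetune()] or
#'   [hf_finetune()]), or a named list of them to overlay optimizers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sae_trace <- function(object, ...) {
  plot_traces(list(trace = object))
}

#' Overlay fine-tuning traces from several optimizers
#'
#' @param traces Named list of `sae_trace` tibbles (e.g.
#'   `list(gd_sae = ..., hf_sae = ...)`).
#' @return A ggplot object with one panel per metric.
#' @export
plot_traces <- function(traces) {
  long <- purrr::imap_dfr(traces, function(tr, nm) {
    tr |>
      dplyr::select("iteration", "train_mse", "train_err", "test_err") |>
      tidyr::pivot_longer(-"iteration", names_to = "metric") |>
      dplyr::mutate(optimizer = nm)
  }) |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("train_mse", "train_err", "test_err"),
                                  labels = c("fine-tuning MSE", "train misclassification",
                                             "test misclassification")))
  ggplot(long, aes(x = .data$iteration, y = .data$value, colour = .data$optimizer)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "outer iteration", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a cross-validation report
#'
#' Per-fold accuracies by method, with the per-method mean overlaid.
#'
#' @param object A `crossval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossval_report <- function(object, ...) {
  ggplot(object$folds,
         aes(x = factor(.data$fold), y = .data$accuracy, fill = .data$method)) +
    geom_col(position = position_dodge()) +
    labs(x = "fold", y = "accuracy (%)", fill = NULL) +
    theme_minimal()
}
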