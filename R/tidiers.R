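#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' @param x A `crossval_report` from [run_crossval()].
#' @param ... Unused.
#' @return One row per method per fold: `method`, `fold`, `n_test`,
#'   `accuracy` (percent).
#' @export
tidy.crossval_report <- function(x, ...) {
  x$folds
}

#' One-row-per-method summary of a cross-validation report
#'
#' @param x A `crossval_report`.
#' @param ... Unused.
#' @return Tibble with `method`, `mean_accuracy` (percent, 2 decimals),
#'   `n_folds`, and `kappa` (from the confusion matrix pooled over folds).
#' @export
glance.crossval_report <- function(x, ...) {
  x$summary
}

#' Tidy a fitted stacked-autoencoder classifier
#'
#' @param x An `sae_model`.
#' @param ... Unused.
#' @return One row per layer: `layer`, `type`, `fan_in`, `fan_out`,
#'   `n_parameters`, and weight summary statistics.
#' @export
tidy.sae_model <- function(x, ...) {
  layers <- c(x$encoder, list(x$head))
  types <- c(rep("encoder", length(x$encoder)),
             if (x$output == "softmax") "softmax" else "linear")
  purrr::map2_dfr(layers, seq_along(layers), function(l, i) {
    tibble(
      layer = i, type = types[i],
      fan_in = nrow(l$W), fan_out = ncol(l$W),
      n_parameters = length(l$W) + length(l$b),
      weight_mean = mean(l$W), weight_sd = sd(as.vector(l$W))
    )
  })
}

#' One-row summary of a fitted stacked-autoencoder classifier
#'
#' @param x An `sae_model`.
#' @param ... Unused.
#' @return Tibble with the architecture string, parameter count, output type
#'   and loss.
#' @export
glance.sae_model <- function(x, ...) {
  tibble(
    architecture = paste(x$architecture, collapse = "-"),
    n_parameters = n_params(x),
    n_classes = x$architecture[length(x$architecture)],
    output = x$output,
    loss = x$loss
  )
}
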