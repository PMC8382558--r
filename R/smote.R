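#' SMOTE oversampling of a sample matrix
#'
#' Synthetic minority oversampling: each synthetic sample is drawn on the line
#' segment between an existing sample and one of its `k_neighbors` nearest
#' same-class neighbors (Euclidean distance), `x_new = x_i + u * (x_nn - x_i)`
#' with `u ~ Uniform(0, 1)`. Here SMOTE is used as augmentation on a balanced
#' design: every class is expanded by the same factor, so a 40-sample,
#' 5-class balanced set with `expansion_factor = 8` becomes 320 samples, 64
#' per class. Original rows are kept unchanged and appear first in the output.
#'
#' @param X Numeric sample matrix (rows are samples) or a feature-table
#'   tibble.
#' @param y Class labels (factor, character, or a labels tibble).
#' @param k_neighbors Number of same-class nearest neighbors to draw from
#'   (default 5). Every class must have at least `k_neighbors + 1` members.
#' @param expansion_factor Target output-to-input size ratio per class
#'   (default 8). Each class with `n_c` originals gains
#'   `round(n_c * (expansion_factor - 1))` synthetic samples.
#' @param seed RNG seed; output is deterministic given the seed.
#'
#' @return A list with `X` (expanded matrix, originals first) and `y`
#'   (expanded factor labels). If `X` was a feature-table tibble, `table` and
#'   `labels` tibbles are returned instead, synthetic samples getting
#'   `synth_` identifiers.
#' @export
#'
#' @examples
#' d <- simulate_metabolome(n_per_class = 8, n_classes = 5, p = 30, seed = 1)
#' aug <- smote_expand(d$table, d$labels, seed = 1)
#' nrow(aug$table)  # 320
smote_expand <- function(X, y, k_neighbors = 5, expansion_factor = 8, seed = 1) {
  tabular <- is.data.frame(X)
  if (tabular) {
    tbl <- X
    y <- as_label_factor(y, tbl)
    X <- ft_values(tbl)
  } else {
    y <- as_label_factor(y)
  }
  if (!is_count(k_neighbors)) sae_abort("k_neighbors must be a positive integer", "bad_config")
  if (!is_number(expansion_factor) || expansion_factor < 1) {
    sae_abort("expansion_factor must be >= 1", "bad_config")
  }
  if (!all(is.finite(X))) sae_abort("SMOTE input must be finite", "non_numeric")
  if (length(y) != nrow(X)) sae_abort("label length does not match sample count", "bad_labels")

  counts <- table(y)
  too_small <- names(counts)[counts < k_neighbors + 1]
  if (length(too_small) > 0) {
    sae_abort(
      paste0("class(es) ", paste(too_small, collapse = ", "), " have fewer than k_neighbors + 1 = ",
             k_neighbors + 1, " members"),
      "class_too_small"
    )
  }

  synth <- with_seed(seed, {
    parts <- lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      n_c <- length(rows)
      n_new <- round(n_c * (expansion_factor - 1))
      if (n_new == 0) {
        return(list(X = X[integer(0), , drop = FALSE], y = character(0)))
      }
      Xc <- X[rows, , drop = FALSE]
      # pairwise distances within the class; each row's k nearest neighbors
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))
      base <- rep_len(seq_len(n_c), n_new)
      pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
      u <- runif(n_new)
      Xnew <- Xc[base, , drop = FALSE] + u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      list(X = Xnew, y = rep(cl, n_new))
    })
    list(
      X = do.call(rbind, lapply(parts, `[[`, "X")),
      y = unlist(lapply(parts, `[[`, "y"))
    )
  })

  X_out <- rbind(X, synth$X)
  y_out <- factor(c(as.character(y), synth$y), levels = levels(y))
  if (!tabular) {
    return(list(X = X_out, y = y_out))
  }
  n_new <- length(synth$y)
  synth_ids <- if (n_new > 0) {
    sprintf("synth_%s_%03d", synth$y, stats::ave(seq_len(n_new), synth$y, FUN = seq_along))
  } else {
    character(0)
  }
  ids <- c(tbl$sample_id, synth_ids)
  list(
    table = new_feature_table(X_out, ids, ft_feature_ids(tbl)),
    labels = tibble(sample_id = ids, label = y_out)
  )
}
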