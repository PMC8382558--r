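#' Assign samples to cross-validation folds
#'
#' Produces a k-fold partition: every sample lands in exactly one test fold,
#' fold sizes differ by at most one, and with `stratified = TRUE` (default)
#' class proportions are preserved within one sample per class per fold.
#'
#' @param labels Class labels (factor, character, or labels tibble).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(labels, k = 5, seed = 1, stratified = TRUE) {
  y <- as_label_factor(labels)
  n <- length(y)
  if (!is_count(k, min = 2)) sae_abort("k must be an integer >= 2", "bad_config")
  if (k > n) sae_abort("k exceeds the number of samples", "bad_config")
  if (stratified && any(table(y) < k)) {
    sae_abort("every class needs at least k members for stratified folds", "bad_config")
  }
  with_seed(seed, {
    if (stratified) {
      # shuffle within class, concatenate classes, then deal folds round-robin
      # over that ordering: global sizes differ by <= 1 and per-class counts
      # differ by <= 1
      ord <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
    } else {
      ord <- sample.int(n)
    }
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Misclassification rate
#'
#' Fraction of positions where prediction and truth disagree; accuracy is
#' `1 - misclassification_rate`.
#'
#' @param pred,truth Equal-length label vectors.
#' @return A rate in `[0, 1]`.
#' @export
misclassification_rate <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    sae_abort("pred and truth must be equal-length, nonempty", "shape_mismatch")
  }
  mean(as.character(pred) != as.character(truth))
}

#' Confusion matrix
#'
#' `K x K` counts with rows indexed by the true class and columns by the
#' predicted class.
#'
#' @param pred,truth Label vectors.
#' @param levels Class levels defining the matrix order; defaults to the
#'   union of levels seen.
#' @return An integer matrix with `dimnames` `(truth, pred)`.
#' @export
confusion_matrix <- function(pred, truth, levels = NULL) {
  levels <- levels %||% sort(union(unique(as.character(truth)), unique(as.character(pred))))
  p <- factor(as.character(pred), levels = levels)
  t_ <- factor(as.character(truth), levels = levels)
  if (anyNA(p) || anyNA(t_)) sae_abort("labels outside the declared level set", "bad_labels")
  m <- table(truth = t_, pred = p)
  matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement (diagonal mass) and `p_e` the agreement expected from
#' the row/column marginals. Equals 1 for a perfectly diagonal matrix and 0
#' when observed agreement matches chance. The degenerate case `p_e = 1`
#' (all mass in one cell) returns 0 with a warning.
#'
#' @param cm A confusion matrix (counts).
#' @return Kappa.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) sae_abort("confusion matrix is empty", "shape_mismatch")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    warn("chance agreement is 1 (single-cell confusion matrix); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' k-nearest-neighbor classifier
#'
#' Majority vote over the `k` Euclidean nearest training samples. Vote ties
#' break to the lowest class index; distance ties to the earliest training
#' row. Deterministic.
#'
#' @param X_train,X_test Numeric matrices with matching feature counts.
#' @param y_train Training labels.
#' @param k Neighbor count (default 5).
#' @return Factor of predicted labels.
#' @export
knn_classify <- function(X_train, y_train, X_test, k = 5) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y <- as_label_factor(y_train)
  if (nrow(X_train) == 0) sae_abort("empty training set", "empty_table")
  if (!is_count(k) || k > nrow(X_train)) sae_abort("k must be in 1..n_train", "bad_config")
  # squared Euclidean distances test x train
  D <- outer(rowSums(X_test^2), rowSums(X_train^2), "+") - 2 * X_test %*% t(X_train)
  idx <- apply(D, 1, function(d) order(d)[seq_len(k)])
  idx <- matrix(idx, nrow = k)
  pred <- apply(idx, 2, function(nn) {
    votes <- tabulate(as.integer(y[nn]), nbins = nlevels(y))
    which.max(votes)  # first max = lowest class index
  })
  factor(levels(y)[pred], levels = levels(y))
}

#' Kernel SVM classifier
#'
#' Thin wrapper over [e1071::svm()] (libsvm): RBF kernel by default,
#' multiclass by one-vs-one voting. Inputs are assumed already normalized,
#' so libsvm's internal scaling is off.
#'
#' @param X_train,X_test Numeric matrices.
#' @param y_train Training labels (at least two classes).
#' @param kernel Kernel name (default `"radial"`).
#' @param cost Soft-margin cost (default 1).
#' @param gamma RBF bandwidth; default `1/ncol(X_train)`.
#' @return Factor of predicted labels.
#' @export
svm_classify <- function(X_train, y_train, X_test, kernel = "radial",
                         cost = 1, gamma = NULL) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y <- as_label_factor(y_train)
  fit <- e1071::svm(X_train, y, kernel = kernel, cost = cost,
                    gamma = gamma %||% 1 / ncol(X_train), scale = FALSE)
  predict(fit, X_test)
}

#' Summarize per-fold accuracies into report means
#'
#' The report aggregator: mean accuracy per method, rounded to 2 decimals as
#' reported (the mean is taken before rounding).
#'
#' @param folds A tibble/data frame with columns `method`, `fold`, and
#'   `accuracy` (percent).
#' @return A tibble with `method`, `mean_accuracy` (2 decimals), and
#'   `n_folds`.
#' @export
#'
#' @examples
#' summarize_fold_accuracies(tibble::tibble(
#'   method = "hf_sae", fold = 1:5,
#'   accuracy = c(93.85, 92.31, 90.77, 93.85, 93.85)
#' ))
summarize_fold_accuracies <- function(folds) {
  folds |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_accuracy = round(mean(.data$accuracy), 2),
      n_folds = dplyr::n(),
      .groups = "drop"
    )
}

#' Pipeline configuration for cross-validation runs
#'
#' Bundles every tunable of the end-to-end pipeline. Defaults reproduce the
#' full-scale protocol (hidden sizes 1000-500-100, learning rate 0.01, 500
#' RBM sweeps, 4000 fine-tuning iterations, SMOTE factor 8); reduce the
#' hidden sizes and iteration counts for desk-scale experiments.
#'
#' @param hidden Hidden layer sizes (default `c(1000, 500, 100)`).
#' @param normalizer `"minmax"` (default) or `"zscore"`.
#' @param smote_factor SMOTE expansion factor; `1` disables augmentation
#'   (default 8).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param paper_order If `TRUE`, SMOTE-expand the full dataset before the CV
#'   split (the protocol that reports 255/65 splits of an already expanded
#'   set); the default `FALSE` applies SMOTE inside each training fold only,
#'   which keeps test folds free of synthetic leakage.
#' @param sparse A [sparse_config()].
#' @param pretrain A [pretrain_config()].
#' @param train A [train_config()] for fine-tuning; `iterations` is the
#'   Hessian-free outer-iteration count.
#' @param gd_iterations Plain gradient-descent fine-tuning budget; defaults
#'   to `train$iterations`. One Hessian-free outer iteration spends many
#'   gradient-equivalents on its inner conjugate-gradient solve, so a
#'   compute-matched comparison typically gives gradient descent a larger
#'   plain-iteration budget.
#' @param hf An [hf_config()].
#' @param head_iters,head_lr Softmax-head training schedule (defaults 500 and
#'   the fine-tuning learning rate).
#' @param knn_k KNN neighbor count (default 5).
#' @param svm_kernel,svm_cost SVM settings (defaults `"radial"`, 1).
#' @param seed Global seed; per-fold and per-stage seeds are derived from it.
#' @return A list of class `sae_pipeline_config`.
#' @export
sae_pipeline_config <- function(hidden = c(1000, 500, 100),
                                normalizer = c("minmax", "zscore"),
                                smote_factor = 8, smote_k = 5,
                                paper_order = FALSE,
                                sparse = sparse_config(),
                                pretrain = pretrain_config(),
                                train = train_config(),
                                gd_iterations = NULL,
                                hf = hf_config(),
                                head_iters = 500, head_lr = NULL,
                                knn_k = 5, svm_kernel = "radial", svm_cost = 1,
                                seed = 1) {
  structure(list(
    hidden = as.integer(hidden), normalizer = match.arg(normalizer),
    smote_factor = smote_factor, smote_k = smote_k, paper_order = isTRUE(paper_order),
    sparse = sparse, pretrain = pretrain, train = train,
    gd_iterations = as.integer(gd_iterations %||% train$iterations), hf = hf,
    head_iters = head_iters, head_lr = head_lr %||% train$learning_rate,
    knn_k = knn_k, svm_kernel = svm_kernel, svm_cost = svm_cost,
    seed = as.integer(seed)
  ), class = "sae_pipeline_config")
}

# Train both SAE variants on one normalized train/test split; returns
# per-method predictions and traces. Pretraining and head training are shared
# so GD and HF fine-tuning start from the identical initialization.
fit_sae_methods <- function(methods, Xtr, ytr, Xte, yte, config, seed) {
  out <- list()
  if (length(methods) == 0) return(out)
  arch <- c(ncol(Xtr), config$hidden, nlevels(ytr))
  pre <- config$pretrain
  pre$seed <- seed
  enc <- pretrain_stack(Xtr, arch, config$sparse, pre)
  H <- Xtr
  for (l in seq_along(enc)) H <- relu(affine_forward(enc[[l]], H))
  head <- train_softmax_head(H, one_hot(ytr), iterations = config$head_iters,
                             learning_rate = config$head_lr, seed = derive_seed(seed, 17))
  model0 <- new_sae_model(arch, enc, head, class_levels = levels(ytr))
  if ("gd_sae" %in% methods) {
    gd_cfg <- config$train
    gd_cfg$iterations <- config$gd_iterations %||% config$train$iterations
    fit <- gd_finetune(model0, Xtr, ytr, Xte, yte, gd_cfg)
    out$gd_sae <- list(pred = predict(fit$model, Xte), trace = fit$trace)
  }
  if ("hf_sae" %in% methods) {
    fit <- hf_finetune(model0, Xtr, ytr, Xte, yte, config$train, config$hf)
    out$hf_sae <- list(pred = predict(fit$model, Xte), trace = fit$trace)
  }
  out
}

evaluate_split <- function(methods, Xtr, ytr, Xte, yte, config, seed) {
  preds <- list()
  traces <- list()
  if ("knn" %in% methods) preds$knn <- knn_classify(Xtr, ytr, Xte, k = config$knn_k)
  if ("svm" %in% methods) {
    preds$svm <- svm_classify(Xtr, ytr, Xte, kernel = config$svm_kernel, cost = config$svm_cost)
  }
  sae <- fit_sae_methods(intersect(methods, c("gd_sae", "hf_sae")),
                         Xtr, ytr, Xte, yte, config, seed)
  for (mth in names(sae)) {
    preds[[mth]] <- sae[[mth]]$pred
    traces[[mth]] <- sae[[mth]]$trace
  }
  list(preds = preds, traces = traces)
}

#' Run the five-fold cross-validation benchmark
#'
#' For each fold: fit the normalizer on the training partition only, apply it
#' to both partitions, SMOTE-expand the training partition (unless
#' `paper_order`), pretrain the encoder stack, train the softmax head,
#' fine-tune by gradient descent and/or Hessian-free optimization, fit the
#' KNN/SVM baselines, and evaluate everything on the untouched test fold. No
#' information from any test fold reaches normalization, SMOTE, pretraining,
#' or fine-tuning in the default (leakage-safe) order.
#'
#' @param table A feature-table tibble.
#' @param labels Labels tibble (or factor).
#' @param methods Subset of `c("knn", "svm", "gd_sae", "hf_sae")`.
#' @param config An [sae_pipeline_config()].
#' @param k Number of folds (default 5).
#' @return A `crossval_report`: list with `folds` (per-method per-fold
#'   accuracy tibble), `summary` (mean accuracy and pooled-confusion kappa
#'   per method), `confusion` (pooled confusion matrices), `traces`
#'   (per-fold fine-tuning traces), plus the config and seed. Has
#'   [generics::tidy()], [generics::glance()], and
#'   [ggplot2::autoplot()] methods.
#' @export
run_crossval <- function(table, labels, methods = c("knn", "svm", "gd_sae", "hf_sae"),
                         config = sae_pipeline_config(), k = 5) {
  methods <- match.arg(methods, c("knn", "svm", "gd_sae", "hf_sae"), several.ok = TRUE)
  y <- as_label_factor(labels, table)
  X_tbl <- table
  if (config$paper_order && config$smote_factor > 1) {
    aug <- smote_expand(X_tbl, labels, k_neighbors = config$smote_k,
                        expansion_factor = config$smote_factor,
                        seed = derive_seed(config$seed, 999))
    X_tbl <- aug$table
    y <- as_label_factor(aug$labels, X_tbl)
  }
  folds <- make_folds(y, k = k, seed = config$seed, stratified = TRUE)
  X_all <- ft_values(X_tbl)

  fold_rows <- list()
  cms <- list()
  traces <- list()
  for (f in seq_len(k)) {
    te <- folds == f
    res <- tryCatch(
      run_fold(X_tbl, X_all, y, te, methods, config, derive_seed(config$seed, f)),
      error = function(e) {
        sae_abort(paste0("fold ", f, " failed: ", conditionMessage(e)), "fold_failure",
                  parent = e)
      }
    )
    for (mth in names(res$preds)) {
      acc <- 100 * (1 - misclassification_rate(res$preds[[mth]], y[te]))
      fold_rows[[length(fold_rows) + 1]] <-
        tibble(method = mth, fold = f, n_test = sum(te), accuracy = acc)
      cm <- confusion_matrix(res$preds[[mth]], y[te], levels = levels(y))
      cms[[mth]] <- if (is.null(cms[[mth]])) cm else cms[[mth]] + cm
    }
    for (mth in names(res$traces)) {
      traces[[mth]][[f]] <- res$traces[[mth]]
    }
  }
  folds_tbl <- dplyr::arrange(dplyr::bind_rows(fold_rows), .data$method, .data$fold)
  summary <- summarize_fold_accuracies(folds_tbl) |>
    dplyr::mutate(kappa = vapply(.data$method, function(mth) cohen_kappa(cms[[mth]]), numeric(1)))
  structure(list(folds = folds_tbl, summary = summary, confusion = cms,
                 traces = traces, methods = methods, k = k, config = config,
                 seed = config$seed),
            class = "crossval_report")
}

run_fold <- function(X_tbl, X_all, y, te, methods, config, seed) {
  tr_tbl <- X_tbl[!te, , drop = FALSE]
  norm <- fit_normalizer(tr_tbl, method = config$normalizer)
  Xtr <- ft_values(apply_normalizer(tr_tbl, norm))
  # held-out values may stray outside [0,1]; they only pass through forward
  # evaluation, never the Bernoulli RBM, so they are kept unclipped
  Xte <- ft_values(apply_normalizer(X_tbl[te, , drop = FALSE], norm))
  ytr <- factor(as.character(y[!te]), levels = levels(y))
  if (!config$paper_order && config$smote_factor > 1) {
    aug <- smote_expand(Xtr, ytr, k_neighbors = config$smote_k,
                        expansion_factor = config$smote_factor,
                        seed = derive_seed(seed, 7))
    Xtr <- aug$X
    ytr <- aug$y
  }
  evaluate_split(methods, Xtr, ytr, Xte, y[te], config, seed)
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("<crossval_report> ", x$k, "-fold, methods: ", paste(x$methods, collapse = ", "),
      "\n\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Shrinking-dataset ablation
#'
#' Re-runs the single-split benchmark on nested stratified subsamples of the
#' (expanded) dataset. For each fraction, `round(n * fraction)` samples are
#' drawn (stratified, seeded), split once into train and test at the 255:65
#' ratio — the training size is scaled and rounded half away from zero, so a
#' 320-sample input yields the size schedule 255/65, 230/58, 204/52, 179/45,
#' 153/39, 128/32 for fractions 1.0 down to 0.5 — and every method is trained
#' once and evaluated on the held-out part.
#'
#' @param table Feature-table tibble (typically already SMOTE-expanded).
#' @param labels Labels tibble or factor.
#' @param fractions Decreasing fractions in `(0, 1]` (default
#'   `seq(1, 0.5, by = -0.1)`).
#' @param methods Methods to run (as in [run_crossval()]).
#' @param config An [sae_pipeline_config()]; SMOTE is not re-applied here.
#' @param train_ratio Training share of each subsample (default `255/320`).
#' @return A tibble with `fraction`, `n_train`, `n_test`, `method`,
#'   `accuracy`.
#' @export
run_size_ablation <- function(table, labels, fractions = seq(1, 0.5, by = -0.1),
                              methods = c("knn", "svm", "gd_sae", "hf_sae"),
                              config = sae_pipeline_config(smote_factor = 1),
                              train_ratio = 255 / 320) {
  methods <- match.arg(methods, c("knn", "svm", "gd_sae", "hf_sae"), several.ok = TRUE)
  if (any(fractions <= 0 | fractions > 1)) sae_abort("fractions must lie in (0, 1]", "bad_config")
  y <- as_label_factor(labels, table)
  n <- length(y)
  rows <- list()
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    sizes <- ablation_sizes(n, fr, train_ratio)
    seed_i <- derive_seed(config$seed, 100 + i)
    keep <- stratified_sample(y, sizes$total, seed_i)
    y_sub <- y[keep]
    tbl_sub <- table[keep, , drop = FALSE]
    tr_idx <- stratified_sample(y_sub, sizes$train, derive_seed(seed_i, 1))
    te <- rep(TRUE, length(y_sub)); te[tr_idx] <- FALSE
    if (!any(te)) sae_abort("fraction too small to leave a test set", "bad_config")
    norm <- fit_normalizer(tbl_sub[!te, , drop = FALSE], method = config$normalizer)
    Xtr <- ft_values(apply_normalizer(tbl_sub[!te, , drop = FALSE], norm))
    Xte <- ft_values(apply_normalizer(tbl_sub[te, , drop = FALSE], norm))
    res <- evaluate_split(methods, Xtr, y_sub[!te], Xte, y_sub[te], config, seed_i)
    for (mth in names(res$preds)) {
      acc <- 100 * (1 - misclassification_rate(res$preds[[mth]], y_sub[te]))
      rows[[length(rows) + 1]] <- tibble(
        fraction = fr, n_train = sizes$train, n_test = sizes$total - sizes$train,
        method = mth, accuracy = acc
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Train/test size schedule for the ablation
#'
#' Scales a dataset of `n` samples by `fraction`, then splits at
#' `train_ratio` with the training size rounded half away from zero.
#'
#' @param n Total sample count.
#' @param fraction Fraction in `(0, 1]`.
#' @param train_ratio Training share (default `255/320`).
#' @return List with `total`, `train`, `test`.
#' @export
ablation_sizes <- function(n, fraction, train_ratio = 255 / 320) {
  total <- as.integer(round_half_away(n * fraction))
  train <- as.integer(round_half_away(total * train_ratio))
  list(total = total, train = train, test = total - train)
}

# Stratified subsample of given total size: per-class quotas proportional to
# class frequencies, largest-remainder rounding, shuffled within class.
stratified_sample <- function(y, size, seed) {
  n <- length(y)
  stopifnot(size <= n)
  quota <- size * table(y) / n
  base <- floor(quota)
  rem <- quota - base
  extra <- size - sum(base)
  if (extra > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[add] <- base[add] + 1
  }
  with_seed(seed, {
    unlist(lapply(seq_along(levels(y)), function(k) {
      idx <- which(y == levels(y)[k])
      idx[sample.int(length(idx), base[k])]
    }), use.names = FALSE)
  })
}
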