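test_that("folds partition the samples evenly and respect strata", {
  y <- factor(rep(c("CG", "MG", "NR", "AK", "PL"), each = 64))
  folds <- make_folds(y, k = 5, seed = 1)
  expect_equal(as.vector(table(folds)), rep(64L, 5))
  expect_equal(sort(unique(folds)), 1:5)
  # every sample in exactly one test fold; per-class proportions within +/- 1
  for (f in 1:5) {
    per_class <- table(y[folds == f])
    expect_true(all(abs(per_class - 64 / 5) <= 1))
  }
  # uneven n: fold sizes differ by at most 1
  y2 <- factor(rep(c("a", "b"), c(17, 16)))
  f2 <- make_folds(y2, k = 5, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  expect_identical(make_folds(y, k = 5, seed = 9), make_folds(y, k = 5, seed = 9))
  expect_error(make_folds(y2, k = 40), class = "metabsae_error_bad_config")
  expect_error(make_folds(factor(rep(c("a", "b"), c(3, 30))), k = 5),
               class = "metabsae_error_bad_config")
})

test_that("misclassification rate complements accuracy", {
  y <- factor(c("a", "b", "a", "b"))
  expect_equal(misclassification_rate(y, y), 0)
  expect_equal(misclassification_rate(y, rev(y)), 1)
  # 65 predictions with 5 errors: accuracy prints as 92.31%
  truth <- factor(rep("a", 65), levels = c("a", "b"))
  pred <- truth; pred[1:5] <- "b"
  rate <- misclassification_rate(pred, truth)
  expect_equal(rate, 5 / 65)
  expect_equal(round(100 * (1 - rate), 2), 92.31)
  expect_error(misclassification_rate(y, y[1:2]), class = "metabsae_error_shape_mismatch")
})

test_that("confusion matrices count truth by prediction", {
  y <- factor(c("a", "b", "c", "a"), levels = c("a", "b", "c"))
  cm <- confusion_matrix(y, y, levels = c("a", "b", "c"))
  expect_equal(diag(cm), c(a = 2L, b = 1L, c = 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  one <- confusion_matrix(factor("b", levels = c("a", "b")), factor("a", levels = c("a", "b")))
  expect_equal(sum(one), 1)
  expect_equal(one["a", "b"], 1L)
  withr::with_seed(4, {
    truth <- factor(sample(letters[1:3], 50, replace = TRUE))
    pred <- factor(sample(letters[1:3], 50, replace = TRUE), levels = levels(truth))
  })
  cm <- confusion_matrix(pred, truth, levels = letters[1:3])
  expect_equal(unname(rowSums(cm)), unname(as.integer(table(truth))))
})

test_that("kappa equals 1 on diagonal agreement and 0 at chance", {
  expect_equal(cohen_kappa(diag(c(13, 13, 13, 13, 13))), 1)
  # observed agreement equals chance agreement: kappa is 0
  chance <- matrix(c(9, 1, 81, 9), 2, 2, byrow = TRUE)
  expect_equal(cohen_kappa(chance), 0)
  # hand evaluation: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  cm <- matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE)
  expect_equal(cohen_kappa(cm), (0.7 - 0.5) / (1 - 0.5))
  # invariant under simultaneous permutation of class labels
  perm <- c(2, 1)
  expect_equal(cohen_kappa(cm[perm, perm]), cohen_kappa(cm))
  expect_warning(k0 <- cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "kappa")
  expect_equal(k0, 0)
})

test_that("KNN votes among the k nearest with deterministic ties", {
  withr::with_seed(5, X <- matrix(rnorm(20 * 3), 20, 3))
  y <- factor(rep(c("a", "b"), each = 10))
  expect_equal(as.character(knn_classify(X, y, X[3, , drop = FALSE], k = 1)), "a")
  # k = n on a balanced set: full tie resolves to the first class
  expect_equal(as.character(knn_classify(X, y, matrix(0, 1, 3), k = 20)), "a")
  # brute-force oracle on 30 random test points
  withr::with_seed(6, {
    Xtr <- matrix(rnorm(25 * 4), 25, 4)
    ytr <- factor(sample(c("u", "v", "w"), 25, replace = TRUE))
    Xte <- matrix(rnorm(30 * 4), 30, 4)
  })
  k <- 5
  pred <- knn_classify(Xtr, ytr, Xte, k = k)
  for (i in 1:30) {
    d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
    nn <- sort.list(d, method = "radix")[1:k]
    votes <- table(ytr[nn])
    expect_equal(as.character(pred[i]), names(votes)[which.max(votes)])
  }
})

test_that("the SVM baseline separates separable data and is deterministic", {
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(40, 4), 20, 2), matrix(rnorm(40, -4), 20, 2))
    y <- factor(rep(c("hi", "lo"), each = 20))
  })
  pred <- svm_classify(X, y, X, kernel = "linear")
  expect_equal(misclassification_rate(pred, y), 0)
  Xte <- X[c(1, 1, 1), ]
  p3 <- svm_classify(X, y, Xte)
  expect_equal(as.character(p3), rep(as.character(p3[1]), 3))
})

test_that("the report aggregator reproduces printed cross-validation means", {
  folds <- tibble::tibble(
    method = rep(c("knn", "svm", "gd_sae", "hf_sae"), each = 5),
    fold = rep(1:5, 4),
    accuracy = c(84.62, 86.15, 81.54, 84.62, 87.69,
                 73.85, 76.92, 81.54, 75.38, 78.46,
                 70.77, 76.92, 73.85, 75.38, 73.85,
                 93.85, 92.31, 90.77, 93.85, 93.85)
  )
  out <- summarize_fold_accuracies(folds)
  expect_equal(out$mean_accuracy[out$method == "hf_sae"], 92.93)
  expect_equal(out$mean_accuracy[out$method == "knn"], 84.92)
  expect_equal(out$mean_accuracy[out$method == "svm"], 77.23)
  expect_equal(out$mean_accuracy[out$method == "gd_sae"], 74.15)
})

test_that("the ablation size schedule matches the scaled 255:65 split", {
  fr <- seq(1, 0.5, by = -0.1)
  sizes <- lapply(fr, function(f) ablation_sizes(320, f))
  expect_equal(vapply(sizes, `[[`, integer(1), "train"),
               c(255L, 230L, 204L, 179L, 153L, 128L))
  expect_equal(vapply(sizes, `[[`, integer(1), "test"),
               c(65L, 58L, 52L, 45L, 39L, 32L))
})

test_that("cross-validation on chance-level data scores near chance for baselines", {
  d <- simulate_metabolome(n_per_class = 12, n_classes = 5, p = 40,
                           effect_size = 0, zero_fraction = 0.2, seed = 40)
  cfg <- sae_pipeline_config(smote_factor = 1, seed = 2)
  rep <- run_crossval(d$table, d$labels, methods = c("knn", "svm"), config = cfg, k = 5)
  expect_equal(nrow(rep$folds), 10)
  # chance is 20%; allow 3 binomial SE on the 60-sample pooled estimate
  band <- 3 * 100 * sqrt(0.2 * 0.8 / 60)
  for (acc in rep$summary$mean_accuracy) {
    expect_lt(abs(acc - 20), band + 5)
  }
  expect_true(all(abs(rep$summary$kappa) < 0.35))
})

test_that("cross-validation bookkeeping is consistent and seed-stable", {
  d <- easy_dataset(seed = 50, p = 40)
  cfg <- sae_pipeline_config(smote_factor = 2, smote_k = 3, seed = 3)
  r1 <- run_crossval(d$table, d$labels, methods = "knn", config = cfg, k = 5)
  r2 <- run_crossval(d$table, d$labels, methods = "knn", config = cfg, k = 5)
  expect_identical(r1$folds, r2$folds)
  expect_equal(sum(r1$folds$n_test), 40)
  expect_equal(tidy(r1), r1$folds)
  expect_equal(glance(r1), r1$summary)
  # mean equals the arithmetic fold mean before rounding
  expect_equal(r1$summary$mean_accuracy, round(mean(r1$folds$accuracy), 2))
})

test_that("the paper-order pipeline expands before splitting", {
  d <- easy_dataset(seed = 60, p = 30)
  cfg <- sae_pipeline_config(smote_factor = 8, paper_order = TRUE, seed = 4)
  rep <- run_crossval(d$table, d$labels, methods = "knn", config = cfg, k = 5)
  expect_equal(sum(rep$folds$n_test), 320)
  expect_equal(unname(rep$folds$n_test), rep(64L, 5))
})

test_that("the size ablation runs the requested schedule", {
  d <- easy_dataset(seed = 70, p = 30)
  aug <- smote_expand(d$table, d$labels, seed = 5)
  cfg <- sae_pipeline_config(smote_factor = 1, seed = 6)
  res <- run_size_ablation(aug$table, aug$labels, fractions = c(1, 0.8, 0.5),
                           methods = "knn", config = cfg)
  expect_equal(nrow(res), 3)
  expect_equal(res$n_train, c(255L, 204L, 128L))
  expect_equal(res$n_test, c(65L, 52L, 32L))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  expect_error(run_size_ablation(aug$table, aug$labels, fractions = c(2)),
               class = "metabsae_error_bad_config")
})
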