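test_that("affine_forward is the weighted sum of inputs plus bias", {
  layer <- sae_layer(matrix(0, 3, 2), c(0, 0))
  expect_equal(affine_forward(layer, matrix(rnorm(6), 2, 3)), matrix(0, 2, 2))
  expect_equal(affine_forward(sae_layer(matrix(2), 1), matrix(3))[1, 1], 7)
  withr::with_seed(1, {
    W <- matrix(rnorm(12), 4, 3); b <- rnorm(3); X <- matrix(rnorm(12), 3, 4)
  })
  out <- affine_forward(sae_layer(W, b), X)
  # element-by-element loop oracle
  ref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) ref[i, j] <- sum(X[i, ] * W[, j]) + b[j]
  expect_equal(out, ref, tolerance = 1e-12)
  expect_error(affine_forward(sae_layer(W, b), matrix(0, 2, 5)),
               class = "metabsae_error_shape_mismatch")
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(matrix(c(-1, 0, 2), 1)), matrix(c(0, 0, 2), 1))
  expect_equal(relu(matrix(-abs(rnorm(12)), 3, 4)), matrix(0, 3, 4))
  Z <- matrix(rnorm(20), 4, 5)
  expect_identical(relu(relu(Z)), relu(Z))
})

test_that("softmax rows are shift-invariant probability vectors", {
  layer <- sae_layer(matrix(0, 3, 5), rep(0, 5))
  P <- softmax_forward(layer, matrix(rnorm(12), 4, 3))
  expect_equal(P, matrix(0.2, 4, 5))
  withr::with_seed(2, {
    layer <- sae_layer(matrix(rnorm(15), 3, 5), rnorm(5))
    H <- matrix(rnorm(30), 10, 3)
  })
  P <- softmax_forward(layer, H)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P > 0))
  shifted <- sae_layer(layer$W, layer$b + 7)  # constant added to all logits
  expect_equal(softmax_forward(shifted, H), P, tolerance = 1e-12)
  # overflow safety
  expect_false(anyNA(softmax_forward(sae_layer(matrix(500, 1, 2), c(0, 0)), matrix(3))))
})

test_that("mse_cost matches hand arithmetic and a per-sample loop oracle", {
  A <- matrix(rnorm(10), 5, 2)
  expect_equal(mse_cost(A, A), 0)
  expect_equal(mse_cost(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 1)
  withr::with_seed(3, { A <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(12), 4, 3) })
  ref <- mean(vapply(1:4, function(k) 0.5 * sum((A[k, ] - Y[k, ])^2), numeric(1)))
  expect_equal(mse_cost(A, Y), ref, tolerance = 1e-12)
  expect_error(mse_cost(A, Y[, 1:2]), class = "metabsae_error_shape_mismatch")
})

test_that("mean_hidden_activation averages per unit over samples", {
  expect_equal(mean_hidden_activation(matrix(0.3, 7, 4)), rep(0.3, 4))
  expect_equal(mean_hidden_activation(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  M <- matrix(runif(30), 6, 5)
  expect_equal(mean_hidden_activation(M),
               vapply(1:5, function(j) sum(M[, j]) / 6, numeric(1)))
})

test_that("the KL sparsity penalty is zero at the target, positive elsewhere", {
  cfg <- sparse_config(rho = 0.05)
  expect_equal(sparsity_penalty(rep(0.05, 10), cfg), 0)
  expect_equal(sparsity_penalty(0.5, cfg),
               0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5))
  for (ph in list(runif(5), c(0, 1, 2), c(1e-9, 0.999999999))) {
    expect_gte(sparsity_penalty(ph, cfg), 0)
  }
})

test_that("the sparse AE cost decomposes into reconstruction MSE plus the penalty", {
  ae <- tiny_ae()
  cfg <- sparse_config(rho = 0.05, beta = 3)
  f <- metabsae:::ae_forward(ae$enc, ae$dec, ae$X)
  expect_equal(
    sparse_ae_cost(ae$enc, ae$dec, ae$X, cfg),
    mse_cost(f$R, ae$X) + cfg$beta * sparsity_penalty(mean_hidden_activation(f$H), cfg)
  )
  cfg0 <- sparse_config(beta = 0)
  expect_equal(sparse_ae_cost(ae$enc, ae$dec, ae$X, cfg0), mse_cost(f$R, ae$X))
  # identity autoencoder on inputs whose mean activation equals the target
  enc1 <- sae_layer(matrix(1), 0)
  dec1 <- sae_layer(matrix(1), 0)
  X1 <- matrix(c(0.04, 0.06))
  expect_equal(sparse_ae_cost(enc1, dec1, X1, sparse_config(rho = 0.05)), 0)
  expect_error(sparse_ae_cost(ae$enc, sae_layer(matrix(0, 4, 5), rep(0, 5)), ae$X),
               class = "metabsae_error_shape_mismatch")
})

test_that("the sparse AE gradient matches central finite differences", {
  ae <- tiny_ae()
  cfg <- sparse_config()
  pack <- function(e, d) c(as.vector(e$W), e$b, as.vector(d$W), d$b)
  unpack <- function(th) list(
    e = sae_layer(matrix(th[1:24], 6, 4), th[25:28]),
    d = sae_layer(matrix(th[29:52], 4, 6), th[53:58])
  )
  g_an <- sparse_ae_gradient(ae$enc, ae$dec, ae$X, cfg)$flat
  g_fd <- fd_grad(function(th) {
    p <- unpack(th); sparse_ae_cost(p$e, p$d, ae$X, cfg)
  }, pack(ae$enc, ae$dec))
  expect_lt(max_rel_err(g_an, g_fd), 1e-6)
})

test_that("the sparsity term's gradient contribution vanishes when beta = 0", {
  ae <- tiny_ae(seed = 43)
  g_sparse <- sparse_ae_gradient(ae$enc, ae$dec, ae$X, sparse_config(beta = 0))$flat
  g_plain <- fd_grad(function(th) {
    e <- sae_layer(matrix(th[1:24], 6, 4), th[25:28])
    d <- sae_layer(matrix(th[29:52], 4, 6), th[53:58])
    mse_cost(metabsae:::ae_forward(e, d, ae$X)$R, ae$X)
  }, c(as.vector(ae$enc$W), ae$enc$b, as.vector(ae$dec$W), ae$dec$b))
  expect_lt(max_rel_err(g_sparse, g_plain), 1e-6)
})

test_that("the gradient is zero at the symmetric zero point", {
  enc <- sae_layer(matrix(0, 3, 2), c(0, 0))
  dec <- sae_layer(matrix(0, 2, 3), c(0, 0, 0))
  g <- sparse_ae_gradient(enc, dec, matrix(0, 4, 3), sparse_config())$flat
  expect_equal(g, rep(0, length(g)))
})

test_that("RBM initialization is seeded, range-checked, and a no-op at zero sweeps", {
  withr::with_seed(5, X <- matrix(runif(20 * 6), 20, 6))
  cfg0 <- pretrain_config(rbm_iters = 0, seed = 3)
  l0 <- rbm_init_layer(X, 4, cfg0)
  ref <- withr::with_seed(3L, metabsae:::init_layer(6, 4))
  expect_equal(l0$W, ref$W)
  expect_equal(l0$b, ref$b)
  cfg <- pretrain_config(rbm_iters = 50, seed = 3)
  l1 <- rbm_init_layer(X, 4, cfg)
  l2 <- rbm_init_layer(X, 4, cfg)
  expect_identical(l1$W, l2$W)
  expect_error(rbm_init_layer(X * 2, 4, cfg), class = "metabsae_error_bad_input_range")
  # Gaussian visible units accept unbounded input
  expect_silent(rbm_init_layer(X * 5 - 2, 3, pretrain_config(rbm_iters = 5, visible = "gaussian", seed = 1)))
})

test_that("CD-1 reduces the one-step reconstruction error on average", {
  drops <- vapply(1:5, function(s) {
    d <- simulate_metabolome(n_per_class = 10, n_classes = 2, p = 40,
                             zero_fraction = 0.2, seed = 100 + s)
    X <- ft_matrix(apply_normalizer(d$table, fit_normalizer(d$table)))
    err <- attr(rbm_init_layer(X, 8, pretrain_config(rbm_iters = 100, seed = s)), "recon_error")
    err[length(err)] - err[1]
  }, numeric(1))
  expect_lt(mean(drops), 0)
})

test_that("greedy pretraining chains layers and feeds activations forward", {
  withr::with_seed(6, X <- matrix(runif(15 * 10), 15, 10))
  sp <- sparse_config()
  pc <- pretrain_config(rbm_iters = 10, ae_iters = 5, seed = 2)
  one <- pretrain_stack(X, c(10, 4, 3), sp, pc)
  expect_length(one, 1)
  expect_equal(dim(one[[1]]$W), c(10, 4))
  two <- pretrain_stack(X, c(10, 4, 3, 2), sp, pc)
  expect_length(two, 2)
  expect_equal(dim(two[[2]]$W), c(4, 3))
  # the first layer is trained independently of how many layers follow
  expect_equal(two[[1]]$W, one[[1]]$W)
  expect_error(pretrain_stack(X, c(9, 4, 2), sp, pc), class = "metabsae_error_shape_mismatch")
})

test_that("sparse-AE refinement descends its cost during pretraining", {
  deltas <- vapply(1:5, function(s) {
    withr::with_seed(s, X <- matrix(runif(20 * 8), 20, 8))
    cfg <- pretrain_config(rbm_iters = 5, ae_iters = 0, seed = s, learning_rate = 0.01)
    sp <- sparse_config()
    enc <- rbm_init_layer(X, 4, cfg)
    dec <- withr::with_seed(1000L + s, metabsae:::init_layer(4, 8))
    c0 <- sparse_ae_cost(enc, dec, X, sp)
    for (i in 1:50) {
      g <- sparse_ae_gradient(enc, dec, X, sp)
      enc$W <- enc$W - 0.01 * g$gW_enc; enc$b <- enc$b - 0.01 * g$gb_enc
      dec$W <- dec$W - 0.01 * g$gW_dec; dec$b <- dec$b - 0.01 * g$gb_dec
    }
    sparse_ae_cost(enc, dec, X, sp) - c0
  }, numeric(1))
  expect_lt(stats::median(deltas), 0)
})

test_that("the softmax head fits linearly separable activations perfectly", {
  withr::with_seed(8, {
    H <- rbind(matrix(rnorm(20 * 2, mean = 3), 20, 2), matrix(rnorm(20 * 2, mean = -3), 20, 2))
    y <- factor(rep(c("pos", "neg"), each = 20), levels = c("pos", "neg"))
  })
  # independent separability oracle: a linear SVM achieves zero training error
  svm_acc <- 1 - misclassification_rate(svm_classify(H, y, H, kernel = "linear"), y)
  expect_equal(svm_acc, 1)
  Y <- metabsae:::one_hot(y)
  head <- train_softmax_head(H, Y, iterations = 2000, learning_rate = 0.5, seed = 1)
  pred <- max.col(softmax_forward(head, H), ties.method = "first")
  expect_equal(pred, as.integer(y))
})

test_that("head training returns its initialization at zero iterations and descends", {
  withr::with_seed(9, { H <- matrix(rnorm(30), 10, 3); Y <- metabsae:::one_hot(factor(rep_len(1:3, 10))) })
  h0 <- train_softmax_head(H, Y, iterations = 0, seed = 4)
  ref <- withr::with_seed(4L, metabsae:::init_layer(3, 3))
  expect_equal(h0$W, ref$W)
  costs <- numeric(50)
  head <- h0
  for (i in 1:50) {
    head <- train_softmax_head(H, Y, iterations = 1, learning_rate = 1e-3, head = head)
    costs[i] <- mse_cost(softmax_forward(head, H), Y)
  }
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("prediction is the argmax with ties to the lowest class index", {
  m <- new_sae_model(c(3, 4), seed = 1, class_levels = c("a", "b", "c", "d"))
  m$head <- sae_layer(matrix(0, 3, 4), rep(0, 4))  # uniform probabilities
  X <- matrix(rnorm(9), 3, 3)
  expect_equal(as.character(predict(m, X)), rep("a", 3))
  m$head$b <- c(0, 1, 0, 0)  # strict maximum at class b
  expect_equal(as.character(predict(m, X)), rep("b", 3))
  mm <- tiny_model()
  P <- predict(mm$model, mm$X, type = "prob")
  expect_equal(as.integer(predict(mm$model, mm$X)), max.col(P, ties.method = "first"))
})

test_that("flatten/unflatten round-trips all parameters in declared order", {
  mm <- tiny_model(arch = c(4, 3, 2), seed = 5)
  th <- metabsae:::flatten_params(mm$model)
  expect_length(th, 4 * 3 + 3 + 3 * 2 + 2)
  # the first block is the first encoder weight matrix, column-major
  expect_equal(th[1:12], as.vector(mm$model$encoder[[1]]$W))
  m2 <- metabsae:::unflatten_params(mm$model, th)
  expect_equal(m2$encoder, mm$model$encoder)
  expect_equal(m2$head, mm$model$head)
  expect_error(metabsae:::unflatten_params(mm$model, th[-1]),
               class = "metabsae_error_shape_mismatch")
})

test_that("models serialize to JSON and round-trip exactly", {
  mm <- tiny_model(arch = c(6, 4, 3), seed = 11)
  norm <- fit_normalizer(random_table(5, 6, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_sae_model(mm$model, path, normalizer = norm, config = list(note = "fixture"))
  back <- load_sae_model(path)
  expect_equal(back$model$architecture, mm$model$architecture)
  expect_identical(back$model$encoder[[1]]$W, mm$model$encoder[[1]]$W)
  expect_identical(back$model$head$b, mm$model$head$b)
  expect_equal(back$normalizer$stats$min, norm$stats$min)
  expect_equal(back$config$note, "fixture")
  expect_error(load_sae_model(tempfile()), class = "metabsae_error_missing_file")
})
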