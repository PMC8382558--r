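#' Layer parameters
#'
#' A dense layer holds a `fan_in x fan_out` weight matrix `W` and a `fan_out`
#' bias vector `b`.
#'
#' @param W Weight matrix.
#' @param b Bias vector (length `ncol(W)`).
#' @return An object of class `sae_layer`.
#' @export
sae_layer <- function(W, b) {
  W <- as.matrix(W)
  b <- as.numeric(b)
  if (length(b) != ncol(W)) sae_abort("bias length must equal ncol(W)", "shape_mismatch")
  if (!all(is.finite(W)) || !all(is.finite(b))) sae_abort("layer parameters must be finite", "non_numeric")
  structure(list(W = W, b = b), class = "sae_layer")
}

# Glorot-style uniform initialization in +/- sqrt(6 / (fan_in + fan_out)),
# used before RBM training and wherever RBM initialization is disabled.
init_layer <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  sae_layer(matrix(runif(fan_in * fan_out, -r, r), fan_in, fan_out), rep(0, fan_out))
}

#' Affine forward pass
#'
#' Computes the weighted sum of inputs plus bias for every unit:
#' `Z = X %*% W + b` (bias broadcast over rows).
#'
#' @param layer An [sae_layer()].
#' @param X Activation matrix, one row per sample, `ncol(X) == nrow(W)`.
#' @return Pre-activation matrix `Z`.
#' @export
affine_forward <- function(layer, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(layer$W)) {
    sae_abort(paste0("input has ", ncol(X), " columns but layer fan-in is ", nrow(layer$W)),
              "shape_mismatch")
  }
  sweep(X %*% layer$W, 2, layer$b, "+")
}

#' Rectified linear activation
#'
#' Elementwise `max(0, z)`. The subgradient convention at 0 is 0, which keeps
#' backpropagation deterministic.
#'
#' @param Z Pre-activation matrix.
#' @return Activation matrix of the same shape.
#' @export
relu <- function(Z) {
  Z * (Z > 0)
}

relu_grad <- function(Z) (Z > 0) * 1

#' Softmax forward pass
#'
#' Affine transform followed by row-wise exponential normalization, computed
#' with max-subtraction for overflow safety. Every output row is a probability
#' vector.
#'
#' @param layer An [sae_layer()].
#' @param H Input activation matrix.
#' @return Class-probability matrix with rows summing to 1.
#' @export
softmax_forward <- function(layer, H) {
  softmax_rows(affine_forward(layer, H))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Mean-squared-error cost
#'
#' `(1/m) * sum_k 0.5 * ||a(x_k) - y_k||^2` over the `m` rows of `A` and `Y`.
#' This is the reconstruction cost during pretraining and, evaluated on
#' softmax outputs against one-hot targets, the fine-tuning loss.
#'
#' @param A Output matrix (one row per sample).
#' @param Y Target matrix of the same shape.
#' @return A scalar.
#' @export
mse_cost <- function(A, Y) {
  A <- as.matrix(A); Y <- as.matrix(Y)
  if (!all(dim(A) == dim(Y))) sae_abort("output and target shapes differ", "shape_mismatch")
  if (nrow(A) == 0) sae_abort("mse_cost needs at least one sample", "shape_mismatch")
  sum((A - Y)^2) / (2 * nrow(A))
}

#' Mean activation of each hidden unit
#'
#' `p_hat_j = (1/m) * sum_i a_j(x_i)`: the average activation of hidden unit
#' `j` over the batch, the quantity the sparsity penalty drives toward the
#' sparsity target.
#'
#' @param A_hidden Hidden activation matrix (one row per sample).
#' @return Numeric vector of per-unit means.
#' @export
mean_hidden_activation <- function(A_hidden) {
  A_hidden <- as.matrix(A_hidden)
  if (nrow(A_hidden) == 0) sae_abort("empty activation matrix", "shape_mismatch")
  colMeans(A_hidden)
}

#' Sparsity settings for autoencoder pretraining
#'
#' @param rho Sparsity target for the mean hidden activation (default 0.05).
#' @param beta Weight of the sparsity penalty in the cost (default 3).
#' @param eps Clamp half-width: mean activations are clamped into
#'   `[eps, 1 - eps]` before the KL penalty, keeping the penalty defined for
#'   unbounded ReLU activations (default 1e-6).
#' @return A list of class `sparse_config`.
#' @export
sparse_config <- function(rho = 0.05, beta = 3, eps = 1e-6) {
  if (!is_number(rho) || rho <= 0 || rho >= 1) sae_abort("rho must be in (0, 1)", "bad_config")
  if (!is_number(beta) || beta < 0) sae_abort("beta must be >= 0", "bad_config")
  if (!is_number(eps) || eps <= 0 || eps >= 0.5) sae_abort("eps must be in (0, 0.5)", "bad_config")
  structure(list(rho = rho, beta = beta, eps = eps), class = "sparse_config")
}

#' KL-divergence sparsity penalty
#'
#' `sum_j [ rho*log(rho/p_hat_j) + (1-rho)*log((1-rho)/(1-p_hat_j)) ]`, the
#' Bernoulli KL divergence between the sparsity target and each unit's mean
#' activation. Mean activations are clamped into `[eps, 1-eps]` first. The
#' penalty is nonnegative and zero iff every clamped mean equals the target.
#'
#' @param p_hat Vector of mean hidden activations.
#' @param config A [sparse_config()].
#' @return A scalar penalty.
#' @export
sparsity_penalty <- function(p_hat, config = sparse_config()) {
  rho <- config$rho
  ph <- pmin(pmax(p_hat, config$eps), 1 - config$eps)
  sum(rho * log(rho / ph) + (1 - rho) * log((1 - rho) / (1 - ph)))
}

# ---- sparse autoencoder -----------------------------------------------------

# Forward pass of a single untied autoencoder: ReLU encoder, ReLU decoder.
ae_forward <- function(encoder, decoder, X) {
  Z1 <- affine_forward(encoder, X)
  H <- relu(Z1)
  Z2 <- affine_forward(decoder, H)
  R <- relu(Z2)
  list(Z1 = Z1, H = H, Z2 = Z2, R = R)
}

#' Sparse autoencoder cost
#'
#' Reconstruction MSE plus `beta` times the KL sparsity penalty on the mean
#' hidden activations. With `beta = 0` this is exactly the reconstruction
#' [mse_cost()].
#'
#' @param encoder,decoder [sae_layer()]s; the decoder's fan-out must equal the
#'   input dimension.
#' @param X Input matrix (one row per sample).
#' @param config A [sparse_config()].
#' @return A scalar cost.
#' @export
sparse_ae_cost <- function(encoder, decoder, X, config = sparse_config()) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(decoder$W)) {
    sae_abort("decoder output dimension must equal input dimension", "shape_mismatch")
  }
  f <- ae_forward(encoder, decoder, X)
  mse_cost(f$R, X) + config$beta * sparsity_penalty(mean_hidden_activation(f$H), config)
}

#' Gradient of the sparse autoencoder cost
#'
#' Exact gradient of [sparse_ae_cost()] with respect to all encoder and
#' decoder parameters, including the sparsity term's contribution through the
#' mean hidden activation. Where a mean activation falls outside the clamp
#' interval the penalty is locally constant and contributes zero gradient.
#'
#' @inheritParams sparse_ae_cost
#' @return A list with matrices/vectors `gW_enc`, `gb_enc`, `gW_dec`,
#'   `gb_dec`, and `flat`, the same values flattened layer by layer
#'   (encoder then decoder; within a layer `W` in column-major order, then
#'   `b`).
#' @export
sparse_ae_gradient <- function(encoder, decoder, X, config = sparse_config()) {
  X <- as.matrix(X)
  m <- nrow(X)
  f <- ae_forward(encoder, decoder, X)
  dR <- (f$R - X) / m
  dZ2 <- dR * relu_grad(f$Z2)
  gW_dec <- crossprod(f$H, dZ2)
  gb_dec <- colSums(dZ2)
  dH <- dZ2 %*% t(decoder$W)

  # sparsity term: d penalty / d p_hat_j, zero where the clamp is active
  ph_raw <- colMeans(f$H)
  ph <- pmin(pmax(ph_raw, config$eps), 1 - config$eps)
  dkl <- ifelse(ph_raw >= config$eps & ph_raw <= 1 - config$eps,
                -config$rho / ph + (1 - config$rho) / (1 - ph), 0)
  dH <- sweep(dH, 2, config$beta * dkl / m, "+")

  dZ1 <- dH * relu_grad(f$Z1)
  gW_enc <- crossprod(X, dZ1)
  gb_enc <- colSums(dZ1)
  list(
    gW_enc = gW_enc, gb_enc = gb_enc, gW_dec = gW_dec, gb_dec = gb_dec,
    flat = c(as.vector(gW_enc), gb_enc, as.vector(gW_dec), gb_dec)
  )
}

# ---- RBM initialization -----------------------------------------------------

#' Pretraining settings
#'
#' @param rbm_iters Full-batch CD-1 sweeps per RBM (default 500). `0` skips
#'   RBM training and keeps the uniform random initialization.
#' @param ae_iters Gradient-descent refinement steps on the sparse
#'   autoencoder cost per layer (default 500).
#' @param learning_rate Step size for both stages (default 0.01).
#' @param visible RBM visible unit type: `"bernoulli"` (default; inputs must
#'   lie in `[0, 1]` and are treated as activation probabilities) or
#'   `"gaussian"` (linear visible units).
#' @param seed RNG seed.
#' @return A list of class `pretrain_config`.
#' @export
pretrain_config <- function(rbm_iters = 500, ae_iters = 500, learning_rate = 0.01,
                            visible = c("bernoulli", "gaussian"), seed = 1) {
  if (!is_count(rbm_iters, min = 0)) sae_abort("rbm_iters must be a nonnegative integer", "bad_config")
  if (!is_count(ae_iters, min = 0)) sae_abort("ae_iters must be a nonnegative integer", "bad_config")
  if (!is_number(learning_rate) || learning_rate <= 0) sae_abort("learning_rate must be > 0", "bad_config")
  structure(list(rbm_iters = rbm_iters, ae_iters = ae_iters,
                 learning_rate = learning_rate, visible = match.arg(visible),
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize a layer by contrastive-divergence RBM training
#'
#' Trains a restricted Boltzmann machine on `X` by full-batch CD-1
#' (one-step contrastive divergence) for `rbm_iters` sweeps at the configured
#' learning rate, and returns the learned weights and hidden biases as the
#' layer's initialization. With Bernoulli visible units the inputs must lie
#' in `[0, 1]` and are treated as activation probabilities. With
#' `rbm_iters = 0` the uniform random initialization is returned unchanged.
#'
#' @param X Input matrix (one row per sample).
#' @param n_hidden Number of hidden units.
#' @param config A [pretrain_config()].
#' @return An [sae_layer()] with attribute `recon_error`, the mean squared
#'   one-step reconstruction error at each sweep.
#' @export
rbm_init_layer <- function(X, n_hidden, config = pretrain_config()) {
  X <- as.matrix(X)
  if (config$visible == "bernoulli" && (min(X) < 0 || max(X) > 1)) {
    sae_abort("Bernoulli visible units require inputs in [0, 1]; normalize first or use visible = \"gaussian\"",
              "bad_input_range")
  }
  m <- nrow(X)
  alpha <- config$learning_rate
  with_seed(config$seed, {
    layer <- init_layer(ncol(X), n_hidden)
    if (config$rbm_iters == 0) {
      attr(layer, "recon_error") <- numeric(0)
      return(layer)
    }
    W <- layer$W
    b_hid <- layer$b
    b_vis <- rep(0, ncol(X))
    err <- numeric(config$rbm_iters)
    for (it in seq_len(config$rbm_iters)) {
      ph <- sigmoid(sweep(X %*% W, 2, b_hid, "+"))
      hs <- (matrix(runif(m * n_hidden), m, n_hidden) < ph) * 1
      if (config$visible == "bernoulli") {
        pv <- sigmoid(sweep(hs %*% t(W), 2, b_vis, "+"))
      } else {
        pv <- sweep(hs %*% t(W), 2, b_vis, "+")
      }
      ph2 <- sigmoid(sweep(pv %*% W, 2, b_hid, "+"))
      W <- W + alpha * (crossprod(X, ph) - crossprod(pv, ph2)) / m
      b_hid <- b_hid + alpha * colMeans(ph - ph2)
      b_vis <- b_vis + alpha * colMeans(X - pv)
      err[it] <- mean((X - pv)^2)
    }
    out <- sae_layer(W, b_hid)
    attr(out, "recon_error") <- err
    out
  })
}

#' Greedy layer-wise pretraining of the encoder stack
#'
#' For each hidden layer of the architecture: initialize the encoder weights
#' with [rbm_init_layer()], refine them by full-batch gradient descent on the
#' sparse autoencoder cost for `ae_iters` steps (against an untied, randomly
#' initialized decoder), then feed the resulting ReLU activations forward as
#' the next layer's training input. Decoders are discarded; only the encoder
#' stack is returned.
#'
#' @param X Training matrix (rows are samples), typically min-max normalized
#'   to `[0, 1]`.
#' @param architecture Integer vector of layer sizes, input first, class
#'   count last, e.g. `c(4573, 1000, 500, 100, 5)`. The hidden layers are the
#'   interior entries.
#' @param sparse A [sparse_config()].
#' @param pretrain A [pretrain_config()].
#' @return A list of encoder [sae_layer()]s, one per hidden layer.
#' @export
pretrain_stack <- function(X, architecture, sparse = sparse_config(),
                           pretrain = pretrain_config()) {
  X <- as.matrix(X)
  architecture <- as.integer(architecture)
  if (length(architecture) < 3) sae_abort("architecture needs input, >=1 hidden, and output sizes", "bad_config")
  if (architecture[1] != ncol(X)) {
    sae_abort("architecture head must equal the input feature count", "shape_mismatch")
  }
  hidden <- architecture[seq(2, length(architecture) - 1)]
  layers <- vector("list", length(hidden))
  input <- X
  for (l in seq_along(hidden)) {
    cfg_l <- pretrain
    cfg_l$seed <- derive_seed(pretrain$seed, l)
    # layers past the first see unbounded ReLU activations
    if (l > 1 && cfg_l$visible == "bernoulli" && (min(input) < 0 || max(input) > 1)) {
      cfg_l$visible <- "gaussian"
    }
    enc <- rbm_init_layer(input, hidden[l], cfg_l)
    enc <- sae_layer(enc$W, enc$b)
    if (pretrain$ae_iters > 0) {
      dec <- with_seed(derive_seed(pretrain$seed, 1000 + l), init_layer(hidden[l], ncol(input)))
      for (it in seq_len(pretrain$ae_iters)) {
        g <- sparse_ae_gradient(enc, dec, input, sparse)
        enc$W <- enc$W - pretrain$learning_rate * g$gW_enc
        enc$b <- enc$b - pretrain$learning_rate * g$gb_enc
        dec$W <- dec$W - pretrain$learning_rate * g$gW_dec
        dec$b <- dec$b - pretrain$learning_rate * g$gb_dec
      }
    }
    layers[[l]] <- enc
    input <- relu(affine_forward(enc, input))
  }
  layers
}

# ---- classifier model -------------------------------------------------------

#' Assemble a stacked-autoencoder classifier
#'
#' Stacks pretrained encoder layers (ReLU activations) under an output layer.
#' The default output is a softmax head trained against one-hot targets with
#' the MSE loss; a linear output (identity activation, plain least-squares
#' MSE) is available for regression-style use and for convex sanity checks of
#' the optimizers.
#'
#' @param architecture Integer vector of layer sizes (input, hidden...,
#'   output).
#' @param encoder_layers List of [sae_layer()]s matching the hidden sizes;
#'   `NULL` for random initialization.
#' @param head Output [sae_layer()]; `NULL` for random initialization.
#' @param output `"softmax"` (default) or `"linear"`.
#' @param loss `"mse"` (default) or `"cross_entropy"` (softmax output only).
#' @param class_levels Optional character vector of class names for
#'   prediction.
#' @param seed Seed for any random initialization.
#' @return An object of class `sae_model`.
#' @export
new_sae_model <- function(architecture, encoder_layers = NULL, head = NULL,
                          output = c("softmax", "linear"),
                          loss = c("mse", "cross_entropy"),
                          class_levels = NULL, seed = 1) {
  output <- match.arg(output)
  loss <- match.arg(loss)
  architecture <- as.integer(architecture)
  if (length(architecture) < 2) sae_abort("architecture needs at least input and output sizes", "bad_config")
  n_enc <- length(architecture) - 2
  with_seed(seed, {
    if (is.null(encoder_layers)) {
      encoder_layers <- lapply(seq_len(max(n_enc, 0)), function(l) {
        init_layer(architecture[l], architecture[l + 1])
      })
    }
    if (is.null(head)) {
      k <- length(architecture)
      head <- init_layer(architecture[k - 1], architecture[k])
    }
  })
  if (length(encoder_layers) != n_enc) {
    sae_abort("number of encoder layers must be length(architecture) - 2", "shape_mismatch")
  }
  for (l in seq_along(encoder_layers)) {
    if (nrow(encoder_layers[[l]]$W) != architecture[l] ||
        ncol(encoder_layers[[l]]$W) != architecture[l + 1]) {
      sae_abort(paste0("encoder layer ", l, " shape does not chain with the architecture"),
                "shape_mismatch")
    }
  }
  k <- length(architecture)
  if (nrow(head$W) != architecture[k - 1] || ncol(head$W) != architecture[k]) {
    sae_abort("head shape does not chain with the architecture", "shape_mismatch")
  }
  structure(list(architecture = architecture, encoder = encoder_layers,
                 head = head, output = output, loss = loss,
                 class_levels = class_levels),
            class = "sae_model")
}

#' @export
print.sae_model <- function(x, ...) {
  cat("<sae_model> ", paste(x$architecture, collapse = "-"),
      " | output:", x$output, "| loss:", x$loss, "\n")
  invisible(x)
}

# Full forward pass; returns all intermediate activations for backprop.
sae_forward <- function(model, X) {
  X <- as.matrix(X)
  A <- vector("list", length(model$encoder) + 1)
  Z <- vector("list", length(model$encoder))
  A[[1]] <- X
  for (l in seq_along(model$encoder)) {
    Z[[l]] <- affine_forward(model$encoder[[l]], A[[l]])
    A[[l + 1]] <- relu(Z[[l]])
  }
  Z_out <- affine_forward(model$head, A[[length(A)]])
  P <- if (model$output == "softmax") softmax_rows(Z_out) else Z_out
  list(A = A, Z = Z, Z_out = Z_out, P = P)
}

# One-hot encode a factor to an n x K matrix.
one_hot <- function(y, levels = NULL) {
  y <- if (is.factor(y)) y else factor(y, levels = levels %||% sort(unique(y)))
  if (!is.null(levels)) y <- factor(as.character(y), levels = levels)
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Fine-tuning loss of the classifier stack.
model_loss <- function(model, X, Y) {
  P <- sae_forward(model, X)$P
  if (model$loss == "mse") {
    mse_cost(P, Y)
  } else {
    -sum(Y * log(pmax(P, 1e-300))) / nrow(as.matrix(X))
  }
}

#' Train the softmax classification head
#'
#' Full-batch gradient descent of the output layer on the fine-tuning loss
#' (MSE between softmax outputs and one-hot targets by default), with the
#' encoder frozen: only the head's weights and biases move.
#'
#' @param H Top-layer hidden activations (one row per sample).
#' @param Y One-hot target matrix.
#' @param iterations Number of gradient steps (default 500).
#' @param learning_rate Step size (default 0.01).
#' @param loss `"mse"` (default) or `"cross_entropy"`.
#' @param seed Seed for the initialization.
#' @param head Optional initial [sae_layer()]; with `iterations = 0` it is
#'   returned unchanged.
#' @return The trained [sae_layer()].
#' @export
train_softmax_head <- function(H, Y, iterations = 500, learning_rate = 0.01,
                               loss = c("mse", "cross_entropy"), seed = 1,
                               head = NULL) {
  loss <- match.arg(loss)
  H <- as.matrix(H); Y <- as.matrix(Y)
  if (nrow(H) != nrow(Y)) sae_abort("H and Y row counts differ", "shape_mismatch")
  head <- head %||% with_seed(seed, init_layer(ncol(H), ncol(Y)))
  m <- nrow(H)
  for (it in seq_len(iterations)) {
    P <- softmax_forward(head, H)
    dZ <- if (loss == "mse") {
      dP <- (P - Y) / m
      P * (dP - rowSums(dP * P))
    } else {
      (P - Y) / m
    }
    head$W <- head$W - learning_rate * crossprod(H, dZ)
    head$b <- head$b - learning_rate * colSums(dZ)
  }
  head
}

#' Predict class labels with a stacked-autoencoder classifier
#'
#' Runs the encoder stack and output layer forward and returns the argmax
#' class per sample; ties break to the lowest class index.
#'
#' @param object An `sae_model`.
#' @param newdata A numeric matrix or feature-table tibble.
#' @param type `"class"` (default) or `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return A factor of predicted labels (or a probability matrix).
#' @export
predict.sae_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) ft_values(newdata) else as.matrix(newdata)
  if (ncol(X) != object$architecture[1]) {
    sae_abort("newdata feature count does not match the model architecture", "shape_mismatch")
  }
  P <- sae_forward(object, X)$P
  if (type == "prob") return(P)
  idx <- max.col(P, ties.method = "first")
  lv <- object$class_levels %||% as.character(seq_len(ncol(P)))
  factor(lv[idx], levels = lv)
}

# ---- parameter flattening ---------------------------------------------------

# Flattening order (shared by all optimizers): encoder layers in order, then
# the head; within each layer all of W in column-major order, then b.
flatten_params <- function(model) {
  layers <- c(model$encoder, list(model$head))
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

unflatten_params <- function(model, theta) {
  layers <- c(model$encoder, list(model$head))
  pos <- 0L
  out <- lapply(layers, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(theta[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- theta[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
  if (pos != length(theta)) sae_abort("parameter vector length mismatch", "shape_mismatch")
  n_enc <- length(model$encoder)
  for (l in seq_len(n_enc)) {
    model$encoder[[l]]$W <- out[[l]]$W
    model$encoder[[l]]$b <- out[[l]]$b
  }
  model$head$W <- out[[n_enc + 1]]$W
  model$head$b <- out[[n_enc + 1]]$b
  model
}

n_params <- function(model) length(flatten_params(model))
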