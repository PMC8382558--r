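#' Fine-tuning settings
#'
#' Full-batch training settings shared by the gradient-descent and
#' Hessian-free fine-tuners. Mini-batching is deliberately not supported:
#' with tens to hundreds of samples the whole batch is used at every step.
#'
#' @param learning_rate Gradient-descent step size (default 0.01; unused by
#'   the Hessian-free fine-tuner).
#' @param iterations Number of (outer) iterations (default 4000).
#' @param seed RNG seed recorded with the run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, iterations = 4000, seed = 1) {
  if (!is_number(learning_rate) || learning_rate <= 0) sae_abort("learning_rate must be > 0", "bad_config")
  if (!is_count(iterations, min = 0)) sae_abort("iterations must be a nonnegative integer", "bad_config")
  structure(list(learning_rate = learning_rate, iterations = as.integer(iterations),
                 seed = as.integer(seed)), class = "train_config")
}

#' Hessian-free optimizer settings
#'
#' Internals of the second-order fine-tuner: the damped Newton system
#' `(G + lambda I) d = -g` is solved approximately by conjugate gradients,
#' `lambda` is adapted by the Levenberg-Marquardt heuristic from the ratio of
#' actual to model-predicted loss reduction, CG is warm-started from the
#' decayed previous solution, and CG backtracking re-evaluates the true loss
#' at stored intermediate iterates and keeps the best.
#'
#' @param lambda_init Initial damping (default 1).
#' @param cg_max_iters Conjugate-gradient iteration budget (default 100).
#' @param cg_tol Relative-residual stopping tolerance (default 5e-4).
#' @param damping_up,damping_down Multipliers applied to `lambda` when the
#'   reduction ratio is poor/good (defaults 1.5 and 1/1.5).
#' @param rho_low,rho_high Reduction-ratio thresholds (defaults 0.25, 0.75).
#' @param cg_backtracking Keep the stored CG iterate with the lowest true
#'   loss instead of the final one (default `TRUE`).
#' @param cg_warm_start_decay Factor applied to the previous solution when
#'   warm-starting CG (default 0.95).
#' @param max_rejections Abort after this many consecutive rejected steps
#'   (default 25).
#' @return A list of class `hf_config`.
#' @export
hf_config <- function(lambda_init = 1, cg_max_iters = 100, cg_tol = 5e-4,
                      damping_up = 1.5, damping_down = 1 / 1.5,
                      rho_low = 0.25, rho_high = 0.75,
                      cg_backtracking = TRUE, cg_warm_start_decay = 0.95,
                      max_rejections = 25) {
  if (!is_number(lambda_init) || lambda_init <= 0) sae_abort("lambda_init must be > 0", "bad_config")
  if (!is_count(cg_max_iters)) sae_abort("cg_max_iters must be a positive integer", "bad_config")
  if (!is_number(cg_tol) || cg_tol <= 0) sae_abort("cg_tol must be > 0", "bad_config")
  if (!(damping_up > 1 && damping_down > 0 && damping_down < 1)) {
    sae_abort("need damping_up > 1 > damping_down > 0", "bad_config")
  }
  if (!(rho_low > 0 && rho_low < rho_high && rho_high < 1)) {
    sae_abort("need 0 < rho_low < rho_high < 1", "bad_config")
  }
  structure(list(lambda_init = lambda_init, cg_max_iters = as.integer(cg_max_iters),
                 cg_tol = cg_tol, damping_up = damping_up, damping_down = damping_down,
                 rho_low = rho_low, rho_high = rho_high,
                 cg_backtracking = isTRUE(cg_backtracking),
                 cg_warm_start_decay = cg_warm_start_decay,
                 max_rejections = as.integer(max_rejections)),
            class = "hf_config")
}

#' One gradient-descent parameter update
#'
#' `params - alpha * grad`, applied jointly to the flattened weight and bias
#' vector.
#'
#' @param params Flat parameter vector.
#' @param grad Flat gradient of the same length.
#' @param alpha Learning rate.
#' @return Updated flat parameter vector.
#' @export
gd_update <- function(params, grad, alpha) {
  if (length(params) != length(grad)) sae_abort("params and grad lengths differ", "shape_mismatch")
  params - alpha * grad
}

#' Gradient of the fine-tuning loss for the whole stack
#'
#' Exact backpropagated gradient of the fine-tuning loss (MSE between the
#' output activations and one-hot targets, by default) with respect to every
#' encoder and head parameter, flattened in the declared order (encoder
#' layers then head; per layer `W` column-major, then `b`).
#'
#' @param model An `sae_model`.
#' @param X Input matrix (one row per sample).
#' @param Y One-hot target matrix.
#' @return Flat gradient vector of length `n_params(model)`.
#' @export
full_model_gradient <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X)
  f <- sae_forward(model, X)
  P <- f$P
  dZ_out <- if (model$output == "linear") {
    (P - Y) / m
  } else if (model$loss == "mse") {
    dP <- (P - Y) / m
    P * (dP - rowSums(dP * P))
  } else {
    (P - Y) / m
  }
  backward_from_output(model, f, dZ_out)
}

# Shared backward sweep: propagate an output-pre-activation sensitivity
# through the stack and collect flattened parameter gradients.
backward_from_output <- function(model, f, dZ_out) {
  A_top <- f$A[[length(f$A)]]
  gW_head <- crossprod(A_top, dZ_out)
  gb_head <- colSums(dZ_out)
  dA <- dZ_out %*% t(model$head$W)
  n_enc <- length(model$encoder)
  gW <- vector("list", n_enc); gb <- vector("list", n_enc)
  for (l in rev(seq_len(n_enc))) {
    dZ <- dA * relu_grad(f$Z[[l]])
    gW[[l]] <- crossprod(f$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(model$encoder[[l]]$W)
  }
  c(unlist(lapply(seq_len(n_enc), function(l) c(as.vector(gW[[l]]), gb[[l]])), use.names = FALSE),
    as.vector(gW_head), gb_head)
}

#' Gauss-Newton curvature-vector product
#'
#' Computes `G v` where `G = (1/m) t(J) H_L J`, `J` is the Jacobian of the
#' network outputs with respect to all parameters and `H_L` the Hessian of
#' the loss with respect to the outputs (the identity for the MSE loss). The
#' product is evaluated matrix-free: a forward R-operator pass propagates the
#' directional derivative of every activation, then a backward pass pulls the
#' loss-space image back through the transposed Jacobian. `G` is positive
#' semidefinite by construction.
#'
#' @param model An `sae_model`.
#' @param v Flat vector of length `n_params(model)`.
#' @param X Input matrix.
#' @param Y One-hot target matrix (unused for the MSE loss, whose
#'   output-space Hessian is constant; kept for interface symmetry).
#' @return Flat vector `G v`.
#' @export
gauss_newton_product <- function(model, v, X, Y = NULL) {
  X <- as.matrix(X)
  if (length(v) != n_params(model)) sae_abort("v length does not match parameter count", "shape_mismatch")
  m <- nrow(X)
  vm <- unflatten_params(model, v)
  f <- sae_forward(model, X)

  # forward R-operator: RA accumulates the directional derivative of each
  # activation along v
  RA <- matrix(0, m, ncol(X))
  for (l in seq_along(model$encoder)) {
    RZ <- f$A[[l]] %*% vm$encoder[[l]]$W + RA %*% model$encoder[[l]]$W
    RZ <- sweep(RZ, 2, vm$encoder[[l]]$b, "+")
    RA <- RZ * relu_grad(f$Z[[l]])
  }
  RZ_out <- f$A[[length(f$A)]] %*% vm$head$W + RA %*% model$head$W
  RZ_out <- sweep(RZ_out, 2, vm$head$b, "+")

  P <- f$P
  if (model$output == "linear") {
    # outputs are the pre-activations; H_L = I
    dZ_out <- RZ_out / m
  } else if (model$loss == "mse") {
    # J includes the softmax Jacobian S (symmetric): Gv = (1/m) Jz' S' S Jz v
    RP <- P * (RZ_out - rowSums(P * RZ_out))
    u <- RP / m
    dZ_out <- P * (u - rowSums(P * u))
  } else {
    # cross-entropy: H_L w.r.t. logits is diag(P) - P P'
    dZ_out <- P * (RZ_out - rowSums(P * RZ_out)) / m
  }
  backward_from_output(model, f, dZ_out)
}

#' Conjugate-gradient solve of the damped Newton system
#'
#' Approximately solves `(G + lambda I) d = -grad` by conjugate gradients
#' from a warm start, stopping at the iteration budget or when the relative
#' residual drops below `cg_tol`. Intermediate iterates are stored at
#' geometrically spaced iterations for CG backtracking.
#'
#' @param apply_G A function of one vector returning `G v` (linear, positive
#'   semidefinite).
#' @param grad Flat gradient vector (the right-hand side is `-grad`).
#' @param lambda Damping added to the diagonal.
#' @param config An [hf_config()].
#' @param x0 Warm-start vector (default zero).
#' @return A list with `solution`, `iterates` (list of stored vectors,
#'   final included), `iters` (their CG iteration indices), and `rel_residual`.
#' @export
cg_solve <- function(apply_G, grad, lambda = 0, config = hf_config(), x0 = NULL) {
  b <- -grad
  n <- length(b)
  x <- x0 %||% numeric(n)
  applyA <- function(v) apply_G(v) + lambda * v
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(solution = numeric(n), iterates = list(numeric(n)), iters = 0L,
                rel_residual = 0))
  }
  r <- b - applyA(x)
  p <- r
  rs <- sum(r^2)
  store_at <- unique(ceiling(1.3^seq_len(60)))
  iterates <- list(); iters <- integer(0)
  i <- 0L
  while (i < config$cg_max_iters && sqrt(rs) > config$cg_tol * bnorm) {
    i <- i + 1L
    Ap <- applyA(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) break  # numerical breakdown / null direction
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (!is.finite(rs_new)) {
      sae_abort("non-finite values in conjugate gradients (raise the damping)", "cg_divergence")
    }
    if (i %in% store_at) {
      iterates[[length(iterates) + 1]] <- x
      iters <- c(iters, i)
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (length(iters) == 0 || iters[length(iters)] != i) {
    iterates[[length(iterates) + 1]] <- x
    iters <- c(iters, i)
  }
  list(solution = x, iterates = iterates, iters = iters,
       rel_residual = sqrt(rs) / bnorm)
}

#' Levenberg-Marquardt damping update
#'
#' Adapts the damping from the reduction ratio `rho` (actual loss reduction
#' divided by the reduction predicted by the damped quadratic model):
#' `rho < rho_low` multiplies `lambda` by `damping_up`, `rho > rho_high` by
#' `damping_down`, otherwise `lambda` is unchanged. A negative (or
#' non-finite) `rho` counts as poor.
#'
#' @param rho Reduction ratio.
#' @param lambda Current damping.
#' @param config An [hf_config()].
#' @return Updated damping.
#' @export
lm_damping_update <- function(rho, lambda, config = hf_config()) {
  if (!is.finite(rho) || rho < config$rho_low) {
    lambda * config$damping_up
  } else if (rho > config$rho_high) {
    lambda * config$damping_down
  } else {
    lambda
  }
}

# ---- fine-tuning drivers ----------------------------------------------------

new_trace <- function(rows) {
  tr <- dplyr::bind_rows(rows)
  class(tr) <- c("sae_trace", class(tr))
  tr
}

trace_row <- function(iteration, model, X_train, Y_train, X_test, Y_test,
                      loss_value, lambda = NA_real_, accepted = NA) {
  pred_tr <- predict(model, X_train)
  truth_tr <- factor(model$class_levels[max.col(Y_train, ties.method = "first")],
                     levels = model$class_levels)
  test_err <- NA_real_
  if (!is.null(X_test)) {
    pred_te <- predict(model, X_test)
    truth_te <- factor(model$class_levels[max.col(Y_test, ties.method = "first")],
                       levels = model$class_levels)
    test_err <- misclassification_rate(pred_te, truth_te)
  }
  tibble(
    iteration = iteration,
    train_mse = loss_value,
    train_err = misclassification_rate(pred_tr, truth_tr),
    test_err = test_err,
    lambda = lambda,
    accepted = accepted
  )
}

prepare_targets <- function(model, y) {
  if (is.matrix(y)) {
    if (is.null(model$class_levels)) model$class_levels <- colnames(y) %||% as.character(seq_len(ncol(y)))
    return(list(model = model, Y = y))
  }
  y <- factor(y, levels = model$class_levels %||% levels(factor(y)))
  if (is.null(model$class_levels)) model$class_levels <- levels(y)
  list(model = model, Y = one_hot(y, model$class_levels))
}

#' Fine-tune the whole stack by full-batch gradient descent
#'
#' Runs `iterations` joint gradient-descent updates of every encoder and head
#' parameter on the fine-tuning loss, recording the loss and the train/test
#' misclassification rates at every iteration.
#'
#' @param model A pretrained `sae_model`.
#' @param X_train,Y_train Training inputs and one-hot targets (or a factor of
#'   labels).
#' @param X_test,Y_test Optional held-out set traced alongside training.
#' @param config A [train_config()].
#' @return A list with the fine-tuned `model` and `trace`, a tibble of class
#'   `sae_trace` with one row per iteration (`iteration`, `train_mse`,
#'   `train_err`, `test_err`, `lambda`, `accepted`; the last two are `NA`
#'   for gradient descent).
#' @export
gd_finetune <- function(model, X_train, Y_train, X_test = NULL, Y_test = NULL,
                        config = train_config()) {
  X_train <- as.matrix(X_train)
  pt <- prepare_targets(model, Y_train); model <- pt$model; Y_train <- pt$Y
  if (!is.null(Y_test) && !is.matrix(Y_test)) Y_test <- one_hot(Y_test, model$class_levels)
  if (!is.null(X_test)) X_test <- as.matrix(X_test)
  rows <- vector("list", config$iterations)
  theta <- flatten_params(model)
  for (it in seq_len(config$iterations)) {
    g <- full_model_gradient(model, X_train, Y_train)
    theta <- gd_update(theta, g, config$learning_rate)
    model <- unflatten_params(model, theta)
    L <- model_loss(model, X_train, Y_train)
    if (!is.finite(L)) {
      sae_abort(paste0("non-finite fine-tuning loss at iteration ", it,
                       " (learning rate too large?)"), "divergence")
    }
    rows[[it]] <- trace_row(it, model, X_train, Y_train, X_test, Y_test, L)
  }
  list(model = model, trace = new_trace(rows))
}

#' Fine-tune the whole stack by Hessian-free optimization
#'
#' Each outer iteration computes the full gradient, approximately solves the
#' damped Gauss-Newton system `(G + lambda I) d = -g` by conjugate gradients
#' (warm-started from the decayed previous solution), backtracks over stored
#' CG iterates to the one with the lowest true loss, adapts `lambda` by the
#' Levenberg-Marquardt rule, and accepts the step only if it does not
#' increase the training loss — so the accepted-step loss sequence is
#' non-increasing by construction. Repeated consecutive rejections beyond
#' `max_rejections` abort with a diagnostic.
#'
#' @inheritParams gd_finetune
#' @param train A [train_config()] (its `iterations` is the outer-iteration
#'   count).
#' @param hf An [hf_config()].
#' @return A list with the fine-tuned `model` and `trace` (`sae_trace`
#'   tibble: `iteration`, `train_mse`, `train_err`, `test_err`, `lambda`,
#'   `accepted`).
#' @export
hf_finetune <- function(model, X_train, Y_train, X_test = NULL, Y_test = NULL,
                        train = train_config(), hf = hf_config()) {
  X_train <- as.matrix(X_train)
  pt <- prepare_targets(model, Y_train); model <- pt$model; Y_train <- pt$Y
  if (!is.null(Y_test) && !is.matrix(Y_test)) Y_test <- one_hot(Y_test, model$class_levels)
  if (!is.null(X_test)) X_test <- as.matrix(X_test)

  lambda <- hf$lambda_init
  theta <- flatten_params(model)
  d_prev <- numeric(length(theta))
  rows <- vector("list", train$iterations)
  L0 <- model_loss(model, X_train, Y_train)
  rejections <- 0L

  for (it in seq_len(train$iterations)) {
    g <- full_model_gradient(model, X_train, Y_train)
    model_it <- model
    applyG <- function(v) gauss_newton_product(model_it, v, X_train, Y_train)
    sol <- cg_solve(applyG, g, lambda, hf, x0 = hf$cg_warm_start_decay * d_prev)

    candidates <- if (hf$cg_backtracking) sol$iterates else list(sol$solution)
    losses <- vapply(candidates, function(d) {
      model_loss(unflatten_params(model, theta + d), X_train, Y_train)
    }, numeric(1))
    best <- which.min(losses)
    d <- candidates[[best]]
    L_new <- losses[best]
    if (!is.finite(L_new)) {
      sae_abort(paste0("non-finite fine-tuning loss at outer iteration ", it), "divergence")
    }

    Gd <- applyG(d)
    pred_red <- -sum(g * d) - 0.5 * sum(d * (Gd + lambda * d))
    rho <- if (pred_red > 0) (L0 - L_new) / pred_red else -Inf
    lambda <- lm_damping_update(rho, lambda, hf)

    accepted <- L_new <= L0
    if (accepted) {
      theta <- theta + d
      model <- unflatten_params(model, theta)
      L0 <- L_new
      d_prev <- d
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
      d_prev <- d
      if (rejections > hf$max_rejections) {
        sae_abort(paste0("Hessian-free step rejected ", rejections,
                         " times in a row at outer iteration ", it), "stalled")
      }
    }
    rows[[it]] <- trace_row(it, model, X_train, Y_train, X_test, Y_test, L0,
                            lambda = lambda, accepted = accepted)
  }
  list(model = model, trace = new_trace(rows))
}

#' Write a training trace to delimited text
#'
#' One row per iteration with columns `iteration`, `train_mse`, `train_err`,
#' `test_err`, `lambda`, `accepted` — the data behind loss/error-per-iteration
#' curves.
#'
#' @param trace An `sae_trace` tibble.
#' @param path Output path.
#' @param delim Delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = "\t") {
  utils::write.table(as.data.frame(trace), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
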