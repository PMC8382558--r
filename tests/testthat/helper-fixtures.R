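# Shared fixtures and independent numeric oracles.

# Central finite-difference gradient of a scalar function.
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Central finite-difference Jacobian of a vector-valued function.
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    as.vector((f(x + e) - f(x - e)) / (2 * h))
  }, numeric(length(f0)))
}

max_rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)

# Small well-formed feature-table file on disk; returns its path.
write_tiny_table <- function(lines = c(
  "sample_id,F1,F2,F3,F4",
  "s1,1,2,3,4",
  "s2,5,6,7,8",
  "s3,0,0.5,1.5,2.5"
)) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random feature-table tibble.
random_table <- function(n = 10, p = 20, seed = 1) {
  withr::with_seed(seed, {
    metabsae:::new_feature_table(
      matrix(rexp(n * p, rate = 0.01), n, p),
      sprintf("s%02d", seq_len(n)),
      sprintf("F%03d", seq_len(p))
    )
  })
}

# Small randomly initialized sparse AE (encoder + decoder) and input batch.
tiny_ae <- function(n_in = 6, n_hid = 4, m = 5, seed = 42) {
  withr::with_seed(seed, list(
    X = matrix(runif(m * n_in, 0.1, 0.9), m, n_in),
    enc = sae_layer(matrix(rnorm(n_in * n_hid, 0, 0.5), n_in, n_hid), rnorm(n_hid, 0, 0.1)),
    dec = sae_layer(matrix(rnorm(n_hid * n_in, 0, 0.5), n_hid, n_in), rnorm(n_in, 0, 0.1))
  ))
}

# Small classifier stack (5-4-3-2 by default: < 60 parameters) with a batch.
# Biases are jittered away from zero so no ReLU pre-activation sits exactly on
# the kink, keeping finite-difference comparisons valid.
tiny_model <- function(arch = c(5, 4, 3, 2), m = 6, seed = 7) {
  model <- new_sae_model(arch, seed = seed)
  withr::with_seed(seed + 1, {
    for (l in seq_along(model$encoder)) {
      model$encoder[[l]]$b <- rnorm(length(model$encoder[[l]]$b), 0.05, 0.05)
    }
    model$head$b <- rnorm(length(model$head$b), 0, 0.05)
    X <- matrix(runif(m * arch[1]), m, arch[1])
    y <- factor(rep_len(seq_len(arch[length(arch)]), m),
                levels = seq_len(arch[length(arch)]))
  })
  list(model = model, X = X, Y = metabsae:::one_hot(y), y = y)
}

# Reduced-scale synthetic study data: easy class structure at p = 200.
easy_dataset <- function(seed = 1, p = 200, n_per_class = 8) {
  simulate_metabolome(n_per_class = n_per_class, n_classes = 5, p = p,
                      n_discriminative = min(25, p %/% 5), effect_size = 2,
                      noise_sd = 1, zero_fraction = 0.3, seed = seed)
}

# Desk-scale pipeline configuration used by end-to-end tests.
test_pipeline_config <- function(seed = 1, iterations_hf = 30, iterations_gd = 300) {
  sae_pipeline_config(
    hidden = c(32, 16),
    pretrain = pretrain_config(rbm_iters = 20, ae_iters = 30, seed = seed),
    train = train_config(iterations = iterations_hf, seed = seed),
    gd_iterations = iterations_gd,
    hf = hf_config(cg_max_iters = 50),
    head_iters = 300,
    seed = seed
  )
}
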