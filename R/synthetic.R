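#' Simulate a metabolomics-like feature table with known class structure
#'
#' Generates nonnegative, sparse, log-normally distributed peak intensities
#' for a balanced multi-class design, mimicking LC-MS feature tables where
#' the feature count far exceeds the sample count. Each class up-shifts its
#' own disjoint block of `n_discriminative` features by `effect_size` on the
#' log scale (a multiplicative intensity effect); all other features are
#' class-uninformative noise. A fraction `zero_fraction` of measurements is
#' then zeroed at random to emulate missing peaks.
#'
#' With `effect_size = 0` the classes are indistinguishable and any classifier
#' should perform at chance; with `effect_size` of at least twice `noise_sd`
#' the classes are nearly linearly separable. The generator therefore spans
#' both regimes used to validate the pipeline.
#'
#' @param n_per_class Samples per class (default 8, a typical animal-study
#'   group size).
#' @param n_classes Number of classes (default 5).
#' @param p Number of features (default 4573; reduce for quick experiments).
#' @param n_discriminative Class-informative features per class (default 25,
#'   reduced to `p %/% n_classes` when p is small).
#'   Requires `n_classes * n_discriminative <= p`.
#' @param effect_size Mean log-intensity up-shift of a class's own block
#'   (default 2).
#' @param noise_sd Log-scale noise standard deviation (default 1).
#' @param zero_fraction Probability that a measurement is zeroed (default 0.3).
#' @param baseline_log_mean,baseline_log_sd Log-scale mean/sd of per-feature
#'   baseline intensities (defaults 4 and 1).
#' @param seed RNG seed; identical seeds give bit-identical output.
#'
#' @return A list with components `table` (feature-table tibble), `labels`
#'   (tibble of `sample_id`, `label`), and `truth` (list with the
#'   per-class discriminative feature indices and the per-feature baseline
#'   log-means).
#' @export
#'
#' @examples
#' d <- simulate_metabolome(n_per_class = 8, n_classes = 5, p = 100, seed = 1)
#' dim(ft_matrix(d$table))
#' table(d$labels$label)
simulate_metabolome <- function(n_per_class = 8,
                                n_classes = 5,
                                p = 4573,
                                n_discriminative = min(25, p %/% n_classes),
                                effect_size = 2,
                                noise_sd = 1,
                                zero_fraction = 0.3,
                                baseline_log_mean = 4,
                                baseline_log_sd = 1,
                                seed = 1) {
  if (!is_count(n_per_class)) sae_abort("n_per_class must be a positive integer", "bad_config")
  if (!is_count(n_classes, min = 2)) sae_abort("n_classes must be an integer >= 2", "bad_config")
  if (!is_count(p)) sae_abort("p must be a positive integer", "bad_config")
  if (!is_count(n_discriminative, min = 0)) sae_abort("n_discriminative must be a nonnegative integer", "bad_config")
  if (n_classes * n_discriminative > p) {
    sae_abort("n_classes * n_discriminative must not exceed p", "bad_config")
  }
  if (!is_number(effect_size) || effect_size < 0) sae_abort("effect_size must be >= 0", "bad_config")
  if (!is_number(noise_sd) || noise_sd < 0) sae_abort("noise_sd must be >= 0", "bad_config")
  if (!is_number(zero_fraction) || zero_fraction < 0 || zero_fraction >= 1) {
    sae_abort("zero_fraction must be in [0, 1)", "bad_config")
  }

  n <- n_per_class * n_classes
  class_names <- if (n_classes == 5) c("CG", "MG", "NR", "AK", "PL") else paste0("C", seq_len(n_classes))
  y <- factor(rep(class_names, each = n_per_class), levels = class_names)

  with_seed(seed, {
    baseline <- rnorm(p, baseline_log_mean, baseline_log_sd)
    disc <- lapply(seq_len(n_classes), function(k) {
      if (n_discriminative == 0) integer(0)
      else seq.int((k - 1) * n_discriminative + 1, k * n_discriminative)
    })
    names(disc) <- class_names
    shift <- matrix(0, n, p)
    for (k in seq_len(n_classes)) {
      rows <- which(as.integer(y) == k)
      shift[rows, disc[[k]]] <- effect_size
    }
    logx <- matrix(rnorm(n * p, 0, noise_sd), n, p)
    logx <- sweep(logx, 2, baseline, "+") + shift
    values <- exp(logx)
    if (zero_fraction > 0) {
      values[matrix(runif(n * p) < zero_fraction, n, p)] <- 0
    }
  })

  sample_ids <- sprintf("%s_%02d", as.character(y), sequence(rep(n_per_class, n_classes)))
  feature_ids <- sprintf("F%04d", seq_len(p))
  list(
    table = new_feature_table(values, sample_ids, feature_ids),
    labels = tibble(sample_id = sample_ids, label = y),
    truth = list(discriminative = disc, baseline_log_mean = baseline)
  )
}
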