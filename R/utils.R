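#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats predict rnorm runif rbinom sd setNames
#' @importFrom utils head tail
NULL

# Condition helper: every user-facing failure carries a metabsae_error_* class
# so callers (and the CLI) can dispatch on it.
sae_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("metabsae_error_", class), "metabsae_error"), ...)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed from a parent seed, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483647L)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
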