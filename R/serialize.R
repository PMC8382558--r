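#' Save or load a stacked-autoencoder model
#'
#' The model — architecture, every weight matrix and bias vector, output
#' type, loss, class levels, and optionally a fitted normalizer — is written
#' as versioned JSON. Numeric values are printed with 17 significant digits,
#' so a save/load round trip reproduces every parameter bit for bit.
#'
#' @param model An `sae_model`.
#' @param path Output path (`.json`).
#' @param normalizer Optional `sae_normalizer` stored alongside the model.
#' @param config Optional configuration list stored verbatim.
#' @return `save_sae_model()`: `path`, invisibly. `load_sae_model()`: a list
#'   with `model`, `normalizer` (or `NULL`), and `config` (or `NULL`).
#' @export
save_sae_model <- function(model, path, normalizer = NULL, config = NULL) {
  stopifnot(inherits(model, "sae_model"))
  enc_layer <- function(l) {
    list(dim = dim(l$W), W = sprintf("%.17g", as.vector(l$W)), b = sprintf("%.17g", l$b))
  }
  payload <- list(
    schema = "metabsae/sae_model",
    schema_version = 1L,
    architecture = model$architecture,
    output = model$output,
    loss = model$loss,
    class_levels = model$class_levels,
    encoder = lapply(model$encoder, enc_layer),
    head = enc_layer(model$head)
  )
  if (!is.null(normalizer)) {
    payload$normalizer <- list(
      method = normalizer$method,
      stats = lapply(as.list(normalizer$stats), function(col) {
        if (is.numeric(col)) sprintf("%.17g", col) else col
      })
    )
  }
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_sae_model
#' @export
load_sae_model <- function(path) {
  if (!file.exists(path)) sae_abort(paste0("model file not found: ", path), "missing_file")
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "metabsae/sae_model")) {
    sae_abort("not a serialized sae_model", "bad_schema")
  }
  if (p$schema_version != 1) {
    sae_abort(paste0("unsupported schema version ", p$schema_version), "bad_schema")
  }
  dec_layer <- function(l) {
    sae_layer(matrix(as.numeric(l$W), l$dim[1], l$dim[2]), as.numeric(l$b))
  }
  enc <- if (length(p$encoder)) lapply(seq_len(nrow_or_len(p$encoder)), function(i) {
    dec_layer(index_layer(p$encoder, i))
  }) else list()
  model <- new_sae_model(as.integer(p$architecture), enc, dec_layer(p$head),
                         output = p$output, loss = p$loss,
                         class_levels = p$class_levels)
  normalizer <- NULL
  if (!is.null(p$normalizer)) {
    stats <- as_tibble(lapply(p$normalizer$stats, function(col) {
      if (is.character(col) && all(grepl("^[-+0-9.eEna]+$", col))) {
        num <- suppressWarnings(as.numeric(col))
        if (!anyNA(num)) num else col
      } else col
    }))
    stats$feature_id <- as.character(p$normalizer$stats$feature_id)
    normalizer <- structure(list(method = p$normalizer$method, stats = stats),
                            class = "sae_normalizer")
  }
  list(model = model, normalizer = normalizer, config = p$config)
}

# jsonlite may simplify a homogeneous list of layer records into a data frame
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
index_layer <- function(x, i) {
  if (is.data.frame(x)) {
    list(dim = unlist(x$dim[i]), W = unlist(x$W[i]), b = unlist(x$b[i]))
  } else {
    x[[i]]
  }
}
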