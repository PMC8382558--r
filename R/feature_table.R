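#' Read a metabolomics feature table
#'
#' A feature table is a delimited text file with samples in rows and features
#' (detected peaks) in columns: the header row holds feature identifiers, the
#' first column (named `sample_id`) holds sample identifiers, and every other
#' cell is a numeric peak intensity. The result is a tibble whose first column
#' is `sample_id` (character) followed by one numeric column per feature.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. `NULL` (default) guesses `","` vs `"\t"` from
#'   the header line.
#' @param missing Policy for empty/NA cells: `"error"` (default) or `"zero"`
#'   (fill with 0; sparse LC-MS tables often encode absence as zero).
#'
#' @return A feature-table tibble (n samples x p features).
#' @export
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,M1,M2", "s1,1.5,0", "s2,2,3.25"), tf)
#' read_feature_table(tf)
read_feature_table <- function(path, delim = NULL, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) {
    sae_abort(paste0("feature table file not found: ", path), "missing_file")
  }
  delim <- delim %||% guess_delim(path)
  lines <- readLines(path)
  if (length(lines) < 2) {
    sae_abort("feature table must have a header row and at least one sample row", "empty_table")
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  # strsplit drops trailing empty fields; pad to the true delimiter count so
  # a missing final cell reads as empty rather than making the row ragged
  widths <- nchar(lines) - nchar(gsub(delim, "", lines, fixed = TRUE)) + 1L
  fields <- lapply(seq_along(fields), function(i) {
    c(fields[[i]], rep("", widths[i] - length(fields[[i]])))
  })
  if (any(widths != widths[1])) {
    sae_abort(
      paste0("ragged rows: header has ", widths[1], " fields but row(s) ",
             paste(which(widths != widths[1]) - 1L, collapse = ", "), " differ"),
      "ragged_rows"
    )
  }
  header <- fields[[1]]
  feature_ids <- header[-1]
  body <- fields[-1]
  sample_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- lapply(body, function(f) f[-1])
  values <- suppressWarnings(
    matrix(as.numeric(unlist(raw)), nrow = length(body), byrow = TRUE)
  )
  blank <- vapply(raw, function(f) any(!nzchar(trimws(f))), logical(1))
  if (anyNA(values) || any(blank)) {
    if (missing == "zero") {
      values[is.na(values)] <- 0
    } else {
      bad <- which(apply(is.na(values), 1, any) | blank)
      nonblank_na <- any(is.na(values[!blank, , drop = FALSE])) ||
        any(vapply(raw[blank], function(f) {
          any(is.na(suppressWarnings(as.numeric(f[nzchar(trimws(f))]))))
        }, logical(1)))
      cls <- if (nonblank_na) "non_numeric" else "missing_values"
      sae_abort(
        paste0("non-numeric or missing cells in row(s) ", paste(bad, collapse = ", ")),
        cls
      )
    }
  }
  new_feature_table(values, sample_ids, feature_ids)
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

# Construct and validate a feature-table tibble from parts.
new_feature_table <- function(values, sample_ids, feature_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(sample_ids)) {
    sae_abort(
      paste0("duplicate sample identifiers: ",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
      "duplicate_ids"
    )
  }
  if (anyDuplicated(feature_ids)) {
    sae_abort(
      paste0("duplicate feature identifiers: ",
             paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")),
      "duplicate_ids"
    )
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    sae_abort("feature table needs at least one sample and one feature", "empty_table")
  }
  if (!all(is.finite(values))) {
    sae_abort("feature table contains non-finite values", "non_numeric")
  }
  out <- as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(out) <- as.character(feature_ids)
  dplyr::bind_cols(tibble(sample_id = as.character(sample_ids)), out)
}

# Extract the numeric matrix (sample ids as rownames) from a feature table.
ft_values <- function(table) {
  stopifnot(is.data.frame(table), names(table)[1] == "sample_id")
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

ft_feature_ids <- function(table) names(table)[-1]

#' Write a feature table to delimited text
#'
#' Values are printed at full double precision (17 significant digits) so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table A feature-table tibble (see [read_feature_table()]).
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delim = ",") {
  values <- ft_values(table)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    sae_abort(paste0("cannot write to ", path), "unwritable_path")
  }
  header <- paste(c("sample_id", ft_feature_ids(table)), collapse = delim)
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], sprintf("%.17g", values[i, ])), collapse = delim)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write a sample label file
#'
#' Labels are stored as two-column delimited text (`sample_id`, `label`), one
#' row per sample.
#'
#' @param path Path to the label file.
#' @param delim Delimiter; `NULL` guesses comma vs tab.
#' @return `read_labels()`: a tibble with columns `sample_id` and `label`
#'   (factor).
#' @export
read_labels <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    sae_abort(paste0("label file not found: ", path), "missing_file")
  }
  delim <- delim %||% guess_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2) sae_abort("label file must have exactly two columns", "bad_labels")
  if (anyDuplicated(df[[1]])) sae_abort("duplicate sample identifiers in label file", "duplicate_ids")
  tibble(sample_id = df[[1]], label = factor(df[[2]]))
}

#' @rdname read_labels
#' @param labels A tibble with columns `sample_id` and `label`.
#' @export
write_labels <- function(labels, path, delim = ",") {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  utils::write.table(
    data.frame(sample_id = labels$sample_id, label = as.character(labels$label)),
    path, sep = delim, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Coerce a label input (tibble, factor, or character) to a factor aligned with
# a feature table.
as_label_factor <- function(labels, table = NULL) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "label") %in% names(labels)))
    if (!is.null(table)) {
      idx <- match(table$sample_id, labels$sample_id)
      if (anyNA(idx)) {
        sae_abort("label file does not cover all samples in the feature table", "bad_labels")
      }
      labels <- labels[idx, ]
    }
    y <- labels$label
  } else {
    y <- labels
  }
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) sae_abort("need at least two classes", "bad_labels")
  if (!is.null(table) && length(y) != nrow(table)) {
    sae_abort("label length does not match number of samples", "bad_labels")
  }
  y
}

#' Fit a per-feature normalization model
#'
#' Statistics are computed from the supplied (training) rows only; apply the
#' fitted model to held-out rows with [apply_normalizer()]. Min-max scaling to
#' `[0, 1]` is the default because downstream RBM initialization treats inputs
#' as Bernoulli activation probabilities on `[0, 1]`.
#'
#' @param table A feature-table tibble.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return An object of class `sae_normalizer` holding per-feature statistics.
#' @export
#'
#' @examples
#' d <- simulate_metabolome(n_per_class = 3, n_classes = 2, p = 10, seed = 1)
#' norm <- fit_normalizer(d$table)
#' rng <- range(ft_matrix(apply_normalizer(d$table, norm)))
#' stopifnot(rng[1] >= 0, rng[2] <= 1)
fit_normalizer <- function(table, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  X <- ft_values(table)
  if (nrow(X) == 0 || ncol(X) == 0) sae_abort("empty feature table", "empty_table")
  if (method == "zscore" && nrow(X) < 2) {
    sae_abort("zscore normalization needs at least two samples", "bad_config")
  }
  stats <- switch(method,
    minmax = tibble(
      feature_id = colnames(X),
      min = unname(apply(X, 2, min)),
      max = unname(apply(X, 2, max))
    ),
    zscore = tibble(
      feature_id = colnames(X),
      mean = unname(colMeans(X)),
      sd = unname(apply(X, 2, sd))
    )
  )
  structure(list(method = method, stats = stats), class = "sae_normalizer")
}

#' Apply a fitted normalization model
#'
#' Held-out values may fall outside `[0, 1]` under min-max scaling; they are
#' preserved unless `clip = TRUE`. Zero-range (constant) features map to 0
#' under min-max; zero-variance features map to 0 under z-scoring.
#'
#' @param table A feature-table tibble whose features match the fitted model.
#' @param model An `sae_normalizer` from [fit_normalizer()].
#' @param clip If `TRUE`, clip min-max output into `[0, 1]`.
#' @return The transformed feature-table tibble.
#' @export
apply_normalizer <- function(table, model, clip = FALSE) {
  stopifnot(inherits(model, "sae_normalizer"))
  X <- ft_values(table)
  if (!identical(colnames(X), model$stats$feature_id)) {
    sae_abort("feature identifiers do not match the fitted normalizer", "feature_mismatch")
  }
  if (model$method == "minmax") {
    rng <- model$stats$max - model$stats$min
    scale <- ifelse(rng > 0, rng, 1)
    Xn <- sweep(sweep(X, 2, model$stats$min, "-"), 2, scale, "/")
    Xn[, rng == 0] <- 0
    if (clip) Xn <- pmin(pmax(Xn, 0), 1)
  } else {
    s <- ifelse(model$stats$sd > 0, model$stats$sd, 1)
    Xn <- sweep(sweep(X, 2, model$stats$mean, "-"), 2, s, "/")
    Xn[, model$stats$sd == 0] <- 0
  }
  new_feature_table(Xn, rownames(X), colnames(X))
}

#' @export
print.sae_normalizer <- function(x, ...) {
  cat("<sae_normalizer> method =", x$method, "|", nrow(x$stats), "features\n")
  invisible(x)
}

#' Extract the numeric intensity matrix from a feature table
#'
#' @param table A feature-table tibble.
#' @return A numeric matrix (samples x features) with sample ids as rownames.
#' @export
ft_matrix <- function(table) ft_values(table)
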