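#' Odds of the negative class for the synthetic benchmark generators
#'
#' Each of the three benchmark generators defines the label law through an
#' odds function of the features: `P(Y = 0 | x) = odds / (1 + odds)`.
#' `dataset1` uses `exp(x0 * x1)`, `dataset2` uses `exp(x2^2 + ... + x5^2 - 4)`
#' and `dataset3` uses `exp(-10 sin(2 x6) + 2|x7| + x8 + exp(-x9))` — the
#' `dataset3` expression is read as log-odds (and exponentiated) so that the
#' probability stays in (0, 1), mirroring the construction of the first two.
#'
#' @param name Generator name: `"dataset1"`, `"dataset2"` or `"dataset3"`.
#' @param x Numeric vector with at least 11 entries (features `x0 ... x10`),
#'   or a matrix with one instance per row.
#' @return The odds of class 0 (always positive); a vector when `x` is a
#'   matrix.
#' @examples
#' logit_value("dataset1", rep(0, 11))          # 1: P(Y = 0) = 0.5
#' logit_value("dataset2", c(0, 0, rep(1, 4), rep(0, 5)))  # exp(0) = 1
#' @export
logit_value <- function(name, x) {
  if (is.matrix(x)) {
    if (ncol(x) < 11L) stop("need at least 11 features (x0..x10)")
    X <- x
  } else {
    if (length(x) < 11L) stop("need at least 11 features (x0..x10)")
    X <- matrix(x, nrow = 1L)
  }
  odds <- switch(name,
    dataset1 = exp(X[, 1L] * X[, 2L]),
    dataset2 = exp(rowSums(X[, 3:6, drop = FALSE]^2) - 4),
    dataset3 = exp(-10 * sin(2 * X[, 7L]) + 2 * abs(X[, 8L]) +
                     X[, 9L] + exp(-X[, 10L])),
    stop("unknown generator name: ", name)
  )
  if (is.matrix(x)) odds else odds[[1L]]
}

#' Ground-truth relevant features of a synthetic generator
#'
#' @param name Generator name.
#' @return Integer vector of 1-based column indices of the features the
#'   generator's label law actually depends on. The columns are named
#'   `x0 ... x10`, so e.g. `dataset1` returns columns 1:2 (features x0, x1).
#' @export
ground_truth <- function(name) {
  switch(name,
    dataset1 = 1:2,   # x0, x1
    dataset2 = 3:6,   # x2..x5
    dataset3 = 7:10,  # x6..x9
    stop("unknown generator name: ", name))
}

#' Construct a tabular dataset object
#'
#' @param features Numeric matrix, one row per instance.
#' @param labels Integer vector of class labels in `0 ... c-1`.
#' @param feature_names Optional character vector of column names.
#' @param relevant_features Optional integer vector of 1-based indices of the
#'   ground-truth relevant features (known for synthetic data).
#' @return A `tabular_dataset` object.
#' @export
tabular_dataset <- function(features, labels, feature_names = NULL,
                            relevant_features = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features has ", nrow(features), " rows but labels has length ",
         length(labels))
  if (is.null(feature_names))
    feature_names <- paste0("x", seq_len(ncol(features)) - 1L)
  if (length(feature_names) != ncol(features))
    stop("feature_names length does not match feature count")
  if (!is.null(relevant_features)) {
    relevant_features <- sort(unique(as.integer(relevant_features)))
    if (any(relevant_features < 1L | relevant_features > ncol(features)))
      stop("relevant_features out of range")
  }
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names,
                 relevant_features = relevant_features),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat("tabular_dataset:", nrow(x$features), "instances x",
      ncol(x$features), "features,", length(unique(x$labels)), "classes\n")
  if (!is.null(x$relevant_features))
    cat("  ground-truth relevant features:",
        paste(x$feature_names[x$relevant_features], collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic benchmark dataset
#'
#' Draws `n_samples` instances with `n_features` i.i.d. standard-normal
#' features and samples each binary label with
#' `P(Y = 0 | x) = odds / (1 + odds)` where the odds come from
#' [logit_value()] for the named generator. Only a fixed subset of features
#' (see [ground_truth()]) enters the label law; the rest are pure noise.
#'
#' @param name Generator name (`"dataset1"`, `"dataset2"`, `"dataset3"`).
#' @param n_samples Number of instances (positive).
#' @param n_features Number of features, at least 11 (default 11: x0..x10,
#'   leaving x10 relevant in no generator).
#' @param seed Integer seed; the same spec and seed reproduce the dataset.
#' @return A [tabular_dataset()] with `relevant_features` set.
#' @examples
#' ds <- generate_dataset("dataset2", 1000, seed = 7)
#' table(ds$labels)
#' @export
generate_dataset <- function(name, n_samples, n_features = 11L, seed = 1L) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (n_features < 11L) stop("n_features must be at least 11")
  relevant <- ground_truth(name)  # validates the name
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  odds <- logit_value(name, X)
  p0 <- odds / (1 + odds)
  y <- ifelse(stats::runif(n_samples) < p0, 0L, 1L)
  tabular_dataset(X, y, relevant_features = relevant)
}

# Save/restore the global RNG state so generation under an explicit seed does
# not disturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Split a dataset into training and test halves
#'
#' The first `floor(n * train_fraction)` rows form the training set and the
#' remainder the test set (rows are already in random order for generated
#' data).
#'
#' @param data A [tabular_dataset()].
#' @param train_fraction Fraction of rows used for training (default 0.5).
#' @return List with elements `train` and `test`, both `tabular_dataset`s.
#' @export
split_dataset <- function(data, train_fraction = 0.5) {
  n <- nrow(data$features)
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n) stop("train_fraction leaves an empty split")
  idx <- seq_len(n_train)
  list(
    train = tabular_dataset(data$features[idx, , drop = FALSE],
                            data$labels[idx], data$feature_names,
                            data$relevant_features),
    test = tabular_dataset(data$features[-idx, , drop = FALSE],
                           data$labels[-idx], data$feature_names,
                           data$relevant_features)
  )
}

#' Write a dataset as delimited text with a JSON sidecar
#'
#' Writes `<path>` as comma-separated text with header `x0,...,label` and a
#' `<path>.json` sidecar recording the generator spec and ground-truth
#' indices (when known).
#'
#' @param data A [tabular_dataset()].
#' @param path Output file path.
#' @param spec Optional named list recorded in the sidecar (e.g. generator
#'   name, n_samples, seed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, spec = NULL) {
  df <- as.data.frame(data$features)
  df$label <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    feature_names = data$feature_names,
    label_column = "label",
    relevant_features = if (is.null(data$relevant_features)) NULL
                        else data$relevant_features,
    spec = spec
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a delimited table into a tabular dataset
#'
#' Reads comma-separated text with a header row. All non-label columns must
#' already be numeric (categorical columns must be pre-encoded). When a
#' `<path>.json` sidecar written by [write_dataset()] exists, the ground-truth
#' relevant features are restored from it.
#'
#' @param path Input file path.
#' @param label_column Name of the label column (default `"label"`).
#' @return A [tabular_dataset()].
#' @export
read_dataset <- function(path, label_column = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  y <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  if (!all(vapply(feats, is.numeric, logical(1L))))
    stop("non-numeric feature columns; encode them before reading")
  relevant <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$relevant_features) && length(meta$relevant_features))
      relevant <- as.integer(meta$relevant_features)
  }
  tabular_dataset(as.matrix(feats), as.integer(y), names(feats), relevant)
}
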