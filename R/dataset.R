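# Discrete sample container and the counting engine. All sample counts used by
# every G-test backend originate here (or are checked against here).

#' Construct a discrete dataset
#'
#' A discrete dataset is an N x M matrix of integer-coded categorical values
#' (0-based), together with per-feature arities and feature names. It is the
#' ground-truth source of all sample counts: direct counting, AD-trees and the
#' entropy cache all answer queries about this object.
#'
#' @param values Integer matrix, N rows (samples) x M columns (features),
#'   entries in `[0, arities[j])`.
#' @param arities Optional integer vector of feature arities; inferred as
#'   `max(column) + 1` when omitted. An arity may exceed the largest observed
#'   value (a legal value can be absent from a finite sample).
#' @param feature_names Optional character vector of unique names; defaults to
#'   column names or `X1..XM`.
#' @return An object of class `discrete_dataset` with elements `values`,
#'   `arities`, `feature_names`, `N`, `M`.
#' @export
discrete_dataset <- function(values, arities = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("dataset must have at least one row and one column")
  if (anyNA(values)) stop("dataset contains missing values")
  if (any(values < 0L)) stop("dataset contains negative values")
  maxv <- apply(values, 2, max)
  if (is.null(arities)) {
    arities <- maxv + 1L
  } else {
    arities <- as.integer(arities)
    if (length(arities) != ncol(values))
      stop("length(arities) must equal the number of features")
    if (any(arities < maxv + 1L))
      stop("arity smaller than an observed value + 1")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values) %||% paste0("X", seq_len(ncol(values)))
  }
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names))
    stop("feature names must be unique")
  colnames(values) <- feature_names
  structure(
    list(values = values, arities = as.integer(arities),
         feature_names = feature_names, N = nrow(values), M = ncol(values)),
    class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("Discrete dataset: %d samples x %d features\n", x$N, x$M))
  cat("  arities:", paste(x$arities, collapse = " "), "\n")
  invisible(x)
}

#' Read a discrete dataset from delimited text
#'
#' Expects a header row of feature names and integer-coded cells (0-based).
#' String categories are not remapped here; use [recode_dataset()] once to
#' convert a table of arbitrary categories. An optional JSON sidecar
#' `{"arities": [...]}` overrides the inferred arities, for values that are
#' legal but absent from the sample.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator (default `,`).
#' @param arities_file Optional path to a JSON sidecar with an `arities` array.
#' @return A [discrete_dataset()].
#' @export
read_discrete_dataset <- function(path, sep = ",", arities_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty table: ", path)
  m <- matrix(NA_integer_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.integer(df[[j]]))
    if (anyNA(v)) {
      r <- which(is.na(v))[1]
      stop(sprintf("cannot parse cell as integer at row %d, column '%s'",
                   r, names(df)[j]))
    }
    if (any(v < 0L)) {
      r <- which(v < 0L)[1]
      stop(sprintf("negative value at row %d, column '%s'", r, names(df)[j]))
    }
    m[, j] <- v
  }
  arities <- NULL
  if (!is.null(arities_file)) {
    side <- jsonlite::read_json(arities_file, simplifyVector = TRUE)
    arities <- as.integer(side$arities)
  }
  discrete_dataset(m, arities = arities, feature_names = names(df))
}

#' Write a discrete dataset as CSV
#'
#' @param ds A [discrete_dataset()].
#' @param path Output path.
#' @param arities_file Optional path for a JSON arity sidecar.
#' @return `path`, invisibly.
#' @export
write_discrete_dataset <- function(ds, path, arities_file = NULL) {
  utils::write.table(ds$values, path, sep = ",", row.names = FALSE,
                     col.names = ds$feature_names, quote = FALSE)
  if (!is.null(arities_file))
    jsonlite::write_json(list(arities = ds$arities), arities_file)
  invisible(path)
}

#' Recode a data frame of arbitrary categories to integer coding
#'
#' One-shot utility mapping each column's sorted unique values to 0..(k-1).
#'
#' @param df A data frame of categorical columns.
#' @return A [discrete_dataset()]; the per-column level maps are attached as
#'   attribute `"levels"`.
#' @export
recode_dataset <- function(df) {
  lv <- lapply(df, function(col) sort(unique(as.character(col))))
  m <- matrix(0L, nrow(df), ncol(df))
  for (j in seq_along(df))
    m[, j] <- match(as.character(df[[j]]), lv[[j]]) - 1L
  ds <- discrete_dataset(m, feature_names = names(df))
  attr(ds, "levels") <- lv
  ds
}

#' Contingency table over a feature subset
#'
#' Sparse table of joint sample counts: zero cells are implicit and never
#' stored, mirroring the AD-tree convention and matching what the
#' degrees-of-freedom rule needs (only observed value combinations count).
#'
#' @param features Integer vector of feature indices (1-based, in query order).
#' @param keys Integer matrix, one row per non-zero cell, one column per
#'   feature in `features` (0-based values).
#' @param counts Positive integer vector of cell counts.
#' @param total Total sample count (`sum(counts)`).
#' @param arities Arities of `features`, same order.
#' @return An object of class `ctab`.
#' @export
contingency_table <- function(features, keys, counts, total, arities) {
  keys <- as.matrix(keys)
  storage.mode(keys) <- "integer"
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop("zero cells must be implicit, not stored")
  if (sum(counts) != total) stop("counts do not sum to total")
  if (ncol(keys) != length(features)) stop("key width != number of features")
  structure(list(features = as.integer(features), keys = keys,
                 counts = counts, total = as.integer(total),
                 arities = as.integer(arities)),
            class = "ctab")
}

#' @export
print.ctab <- function(x, ...) {
  cat(sprintf("Contingency table over features (%s): %d non-zero cells, N = %d\n",
              paste(x$features, collapse = ","), length(x$counts), x$total))
  invisible(x)
}

#' Count the joint occurrences of a feature subset
#'
#' Scans the dataset once and tallies every observed value combination of the
#' requested features. Permutation-covariant: permuting `features` permutes
#' the key columns identically.
#'
#' @param ds A [discrete_dataset()].
#' @param features Non-empty integer vector of feature indices (1-based).
#' @return A [contingency_table()] with `total = ds$N`.
#' @export
count_joint <- function(ds, features) {
  features <- as.integer(features)
  if (length(features) == 0L)
    stop("features must be non-empty; use ds$N for the empty query")
  if (any(features < 1L | features > ds$M)) stop("feature index out of range")
  if (anyDuplicated(features)) stop("duplicate feature index")
  ar <- ds$arities[features]
  sub <- ds$values[, features, drop = FALSE]
  code <- encode_cells(sub, ar)
  tab <- tabulate(code, nbins = prod(ar))
  nz <- which(tab > 0L)
  # decode cell ids back to value tuples
  keys <- matrix(0L, length(nz), length(features))
  rem <- nz - 1
  for (j in seq_along(features)) {
    keys[, j] <- as.integer(rem %% ar[j])
    rem <- rem %/% ar[j]
  }
  contingency_table(features, keys, tab[nz], ds$N, ar)
}

#' Marginalize a contingency table onto a subset of its features
#'
#' Sums counts over the dropped coordinates; the total is preserved, so
#' projection commutes with [count_joint()].
#'
#' @param ct A [contingency_table()].
#' @param keep Non-empty subset of `ct$features` to keep.
#' @return A [contingency_table()] over `keep` (in the order given).
#' @export
project_counts <- function(ct, keep) {
  keep <- as.integer(keep)
  pos <- match(keep, ct$features)
  if (length(keep) == 0L || anyNA(pos))
    stop("keep must be a non-empty subset of the table's features")
  ar <- ct$arities[pos]
  sub <- ct$keys[, pos, drop = FALSE]
  code <- encode_cells(sub, ar)
  agg <- rowsum(as.numeric(ct$counts), group = code)
  ids <- as.numeric(rownames(agg))
  keys <- matrix(0L, length(ids), length(keep))
  rem <- ids - 1
  for (j in seq_along(keep)) {
    keys[, j] <- as.integer(rem %% ar[j])
    rem <- rem %/% ar[j]
  }
  contingency_table(keep, keys, as.integer(agg[, 1]), ct$total, ar)
}
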