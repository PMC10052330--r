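#' Labelled tabular dataset
#'
#' The common currency between all pipeline stages: a numeric feature matrix
#' (missing entries are `NA`, never a sentinel value), integer-coded class
#' labels, and the feature/class name vocabularies. Class labels are mapped to
#' dense codes `1..a` in first-seen order (or the order of `class_names` when
#' supplied), which keeps the encoding deterministic across runs.
#'
#' @param features Numeric matrix or data frame, rows = observations.
#' @param labels Vector of class labels, one per row; coerced to character.
#' @param feature_names Optional character vector of unique feature names;
#'   defaults to the matrix column names or `f1..fn`.
#' @param class_names Optional character vector fixing the class code order;
#'   defaults to first-seen order of `labels`.
#' @return An object of class `asv_dataset` with elements `features`
#'   (N x n double matrix), `labels` (integer codes 1..a), `feature_names`,
#'   `class_names`.
#' @export
#' @examples
#' ds <- asv_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' n_obs(ds); n_classes(ds)
asv_dataset <- function(features, labels, feature_names = NULL,
                        class_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1 || ncol(features) < 1) {
    stop("dataset needs at least one row and one feature column")
  }
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("f", seq_len(ncol(features)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(features)) {
    stop("feature_names length does not match the number of feature columns")
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop("labels length does not match the number of rows")
  }
  class_names <- as.character(class_names %||% unique(labels))
  if (!all(labels %in% class_names)) {
    stop("labels reference classes not listed in class_names")
  }
  dimnames(features) <- NULL
  structure(
    list(
      features = features,
      labels = match(labels, class_names),
      feature_names = feature_names,
      class_names = class_names
    ),
    class = "asv_dataset"
  )
}

#' @rdname asv_dataset
#' @param ds An `asv_dataset`.
#' @export
n_obs <- function(ds) nrow(ds$features)

#' @rdname asv_dataset
#' @export
n_features <- function(ds) ncol(ds$features)

#' @rdname asv_dataset
#' @export
n_classes <- function(ds) length(ds$class_names)

#' @rdname asv_dataset
#' @export
label_names <- function(ds) ds$class_names[ds$labels]

#' @export
print.asv_dataset <- function(x, ...) {
  cat(sprintf(
    "asv_dataset: %d obs x %d features, %d classes (%s), %.1f%% missing\n",
    n_obs(x), n_features(x), n_classes(x),
    paste(x$class_names, collapse = ", "),
    100 * mean(is.na(x$features))
  ))
  invisible(x)
}

ds_subset <- function(ds, idx) {
  asv_dataset(ds$features[idx, , drop = FALSE],
              ds$class_names[ds$labels[idx]],
              feature_names = ds$feature_names,
              class_names = ds$class_names)
}

#' Read a labelled dataset from CSV
#'
#' Expects an RFC 4180 CSV with a header row. Cells of feature columns equal
#' to `missing_token` become missing (`NA`); any other non-numeric feature
#' cell is an error. The label column may hold arbitrary strings.
#'
#' @param path Path to an existing CSV file.
#' @param label_column Name of the class-label column (must be in the header).
#' @param missing_token String marking a missing cell (default `"NA"`).
#' @return An [asv_dataset].
#' @export
read_csv_dataset <- function(path, label_column, missing_token = "NA") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) stop("ragged CSV: rows have differing field counts")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  if (nrow(raw) == 0) stop("CSV contains a header but no data rows")
  if (!label_column %in% names(raw)) {
    stop(sprintf("label column '%s' not found in header", label_column))
  }
  labels <- raw[[label_column]]
  feat_raw <- raw[, setdiff(names(raw), label_column), drop = FALSE]
  if (ncol(feat_raw) == 0) stop("CSV has no feature columns")
  feats <- matrix(NA_real_, nrow(feat_raw), ncol(feat_raw))
  for (j in seq_len(ncol(feat_raw))) {
    v <- feat_raw[[j]]
    miss <- v == missing_token
    num <- suppressWarnings(as.numeric(v))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in feature column '%s'",
                   v[which(bad)[1]], names(feat_raw)[j]))
    }
    num[miss] <- NA_real_
    feats[, j] <- num
  }
  asv_dataset(feats, labels, feature_names = names(feat_raw))
}

#' Write a labelled dataset to CSV
#'
#' Inverse of [read_csv_dataset()]: numeric cells are printed with full
#' double precision (17 significant digits) so read -> write -> read is a
#' fixed point, and missing entries are written as `missing_token`.
#'
#' @param ds An [asv_dataset].
#' @param path Output path.
#' @param label_column Name for the label column (default `"label"`).
#' @param missing_token String to write for missing cells.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path, label_column = "label",
                              missing_token = "NA") {
  stopifnot(inherits(ds, "asv_dataset"))
  if (label_column %in% ds$feature_names) {
    stop("label_column clashes with a feature name")
  }
  cols <- lapply(seq_len(n_features(ds)), function(j) {
    v <- ds$features[, j]
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- missing_token
    out
  })
  names(cols) <- ds$feature_names
  cols[[label_column]] <- label_names(ds)
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic train/test split
#'
#' Splits the rows of a dataset into a training and a test part. With
#' `stratified = TRUE` (the default) the split is drawn per class, so class
#' proportions in the test part match the parent within rounding (each
#' per-class test count is `round(test_fraction * class size)`).
#'
#' @param ds An [asv_dataset] with at least 2 rows.
#' @param test_fraction Fraction of rows assigned to the test part,
#'   strictly inside (0, 1).
#' @param seed Integer seed; identical seeds reproduce identical splits.
#' @param stratified Draw the split within each class (default `TRUE`);
#'   requires every class to have at least 2 members.
#' @return A list of class `asv_split` with elements `train`, `test`
#'   (both [asv_dataset]) and `seed`.
#' @export
split_dataset <- function(ds, test_fraction, seed, stratified = TRUE) {
  stopifnot(inherits(ds, "asv_dataset"))
  stop_if_not_scalar_number(test_fraction, "test_fraction")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly inside (0, 1)")
  }
  N <- n_obs(ds)
  if (N < 2) stop("need at least 2 rows to split")
  test_idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(seq_along(ds$class_names), function(k) {
        rows <- which(ds$labels == k)
        if (length(rows) > 0 && length(rows) < 2) {
          stop(sprintf("class '%s' has fewer than 2 members; cannot stratify",
                       ds$class_names[k]))
        }
        nk <- round(test_fraction * length(rows))
        if (nk == 0) integer(0) else sample(rows, nk)
      }))
    } else {
      sample.int(N, round(test_fraction * N))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(N), test_idx)
  if (!length(train_idx) || !length(test_idx)) {
    stop("split produced an empty part; adjust test_fraction")
  }
  structure(
    list(train = ds_subset(ds, train_idx), test = ds_subset(ds, test_idx),
         seed = as.integer(seed), test_idx = test_idx),
    class = "asv_split"
  )
}
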