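#' Fit the normalization / imputation stage on training data
#'
#' Learns, per feature, the observed non-missing extremes `d_min`/`d_max`
#' and an imputation value (median or mean of the non-missing training
#' values). Applying the fitted transform maps each value x to
#' `(x - d_min) / (d_max - d_min) * (new_max - new_min) + new_min`, so
#' training-range values land in `[new_min, new_max]` (the conventional
#' 0..1 range by default). Fitting only ever sees training data; test data
#' are transformed with the stored parameters, which prevents leakage.
#'
#' @param train An [asv_dataset]; every feature needs at least one
#'   non-missing value.
#' @param new_min,new_max Target range, `new_min < new_max` (defaults 0, 1).
#' @param impute `"median"` (default), `"mean"`, or `"none"` (missing values
#'   are left as `NA`; downstream stages will then refuse them).
#' @param clip Clip transformed values outside `[new_min, new_max]` (out-of-
#'   training-range test values) back into the range. Default `TRUE`.
#' @return An object of class `asv_preprocessor`.
#' @export
#' @examples
#' ds <- asv_dataset(matrix(c(2, 4, 6, 1, 1, 1), 3, 2), c("a", "a", "b"))
#' pp <- fit_preprocessor(ds)
#' apply_preprocessor(pp, ds)$features
fit_preprocessor <- function(train, new_min = 0, new_max = 1,
                             impute = c("median", "mean", "none"),
                             clip = TRUE) {
  stopifnot(inherits(train, "asv_dataset"))
  impute <- match.arg(impute)
  stop_if_not_scalar_number(new_min, "new_min")
  stop_if_not_scalar_number(new_max, "new_max")
  if (new_min >= new_max) stop("new_min must be strictly below new_max")
  X <- train$features
  d_min <- d_max <- imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j][!is.na(X[, j])]
    if (!length(v)) {
      stop(sprintf("feature '%s' is entirely missing in the training data",
                   train$feature_names[j]))
    }
    d_min[j] <- min(v)
    d_max[j] <- max(v)
    imp[j] <- switch(impute, median = stats::median(v), mean = mean(v),
                     none = NA_real_)
  }
  structure(
    list(d_min = d_min, d_max = d_max, new_min = new_min, new_max = new_max,
         impute = impute, impute_values = imp, clip = clip,
         feature_names = train$feature_names),
    class = "asv_preprocessor"
  )
}

#' Apply a fitted preprocessor to a dataset
#'
#' Missing entries are replaced by the stored per-feature imputation value
#' (unless `impute = "none"` was fitted), then min-max scaled into the target
#' range. Constant training features (`d_max == d_min`) map to `new_min` for
#' every input, which keeps the transform defined without NaN propagation.
#'
#' @param params An `asv_preprocessor` from [fit_preprocessor()].
#' @param ds An [asv_dataset] with the same feature columns (count and names)
#'   as the fitting data.
#' @return A transformed [asv_dataset].
#' @export
apply_preprocessor <- function(params, ds) {
  stopifnot(inherits(params, "asv_preprocessor"), inherits(ds, "asv_dataset"))
  if (n_features(ds) != length(params$d_min)) {
    stop("feature count differs from the fitted preprocessor")
  }
  if (!identical(ds$feature_names, params$feature_names)) {
    missing_cols <- setdiff(params$feature_names, ds$feature_names)
    if (length(missing_cols)) {
      stop(sprintf("dataset lacks fitted feature column(s): %s",
                   paste(missing_cols, collapse = ", ")))
    }
    stop("feature columns are ordered differently than at fit time")
  }
  X <- ds$features
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (params$impute != "none") v[is.na(v)] <- params$impute_values[j]
    span <- params$d_max[j] - params$d_min[j]
    v <- if (span == 0) {
      rep(params$new_min, length(v))
    } else {
      (v - params$d_min[j]) / span * (params$new_max - params$new_min) +
        params$new_min
    }
    if (params$clip) v <- pmin(pmax(v, params$new_min), params$new_max)
    X[, j] <- v
  }
  asv_dataset(X, label_names(ds), feature_names = ds$feature_names,
              class_names = ds$class_names)
}
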