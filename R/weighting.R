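#' Equal-frequency discretization of a continuous feature
#'
#' The chi-squared association statistic counts joint occurrences of feature
#' levels and class labels, so continuous features must first be binned.
#' Equal-frequency edges (training quantiles at `1/bins .. (bins-1)/bins`)
#' are robust to skewed distributions; duplicate quantiles (heavily tied
#' data) are merged, so the achieved number of levels `m` can be below
#' `bins`. Pass the stored `edges` back in to code test-time values with the
#' training bins.
#'
#' @param values Numeric vector (no `NA`; impute first).
#' @param bins Target number of bins, at least 2.
#' @param edges Optional previously fitted edges; when supplied, `bins` is
#'   ignored and codes are assigned by these edges.
#' @return A list with `codes` (integer levels `1..m`, where values
#'   `<= edges[i]` fall in bins `1..i`) and `edges`.
#' @export
#' @examples
#' discretize_feature(1:10, bins = 2)
discretize_feature <- function(values, bins = 5, edges = NULL) {
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing")
  }
  if (is.null(edges)) {
    if (bins < 2) stop("bins must be at least 2")
    qs <- stats::quantile(values, probs = seq_len(bins - 1) / bins,
                          names = FALSE, type = 7)
    edges <- unique(qs)
    if (length(edges) == 1 && edges == max(values) && edges == min(values)) {
      edges <- numeric(0)  # constant feature: a single level
    }
  }
  codes <- findInterval(values, edges, left.open = TRUE) + 1L
  list(codes = codes, edges = edges)
}

#' Chi-squared association between a discrete feature and the class label
#'
#' Builds the observed contingency table `O_ij` of joint counts over feature
#' levels i and class levels j, the expected counts under independence
#' `e_ij = count(A = a_i) * count(C = c_j) / N`, and the statistic
#' `chi^2 = sum_ij (O_ij - e_ij)^2 / e_ij`. Cells with `e_ij = 0` contribute
#' 0 (they can arise when a level or class is absent in a bootstrap sample).
#' A feature distributed identically in every class gives exactly 0.
#'
#' @param codes Vector of feature levels.
#' @param labels Vector of class labels, same length.
#' @return A list of class `contingency_chisq`: `statistic` (chi-squared
#'   value, >= 0), `observed`, `expected` (matrices levels x classes), `n`.
#' @export
#' @examples
#' chi_squared_weight(rep(1:2, each = 20), rep(c("a", "b"), each = 20))$statistic
chi_squared_weight <- function(codes, labels) {
  if (length(codes) != length(labels)) {
    stop("codes and labels must have the same length")
  }
  if (!length(codes)) stop("empty input")
  O <- unclass(table(level = factor(codes), class = factor(labels)))
  N <- sum(O)
  e <- outer(rowSums(O), colSums(O)) / N
  contrib <- (O - e)^2 / e
  contrib[e == 0] <- 0
  structure(list(statistic = sum(contrib), observed = O, expected = e, n = N),
            class = "contingency_chisq")
}

#' Chi-squared weights for every feature of a dataset
#'
#' Discretizes each feature by equal-frequency binning (edges fitted on this
#' data and stored for reuse) and scores it with [chi_squared_weight()]
#' against the class label. The rank order sorts weights non-increasingly,
#' ties broken by ascending feature index, and is what drives both the
#' top-`beta * n` selection and the biased per-tree subsampling of the forest.
#'
#' @param ds An [asv_dataset] without missing values.
#' @param bins Bins per feature for discretization (default 5).
#' @return An object of class `feature_weights`: `weights` (named, >= 0),
#'   `order` (feature indices by decreasing weight), `edges` (per-feature
#'   list), `bins`.
#' @export
compute_feature_weights <- function(ds, bins = 5) {
  stopifnot(inherits(ds, "asv_dataset"))
  if (anyNA(ds$features)) stop("missing values present; impute first")
  n <- n_features(ds)
  weights <- numeric(n)
  edges <- vector("list", n)
  for (j in seq_len(n)) {
    d <- discretize_feature(ds$features[, j], bins = bins)
    edges[[j]] <- d$edges
    weights[j] <- chi_squared_weight(d$codes, ds$labels)$statistic
  }
  names(weights) <- ds$feature_names
  structure(
    list(weights = weights, order = order(-weights, seq_len(n)),
         edges = edges, bins = bins),
    class = "feature_weights"
  )
}

#' Select the top beta * n features by weight
#'
#' Returns the `n' = max(1, round(beta * n))` highest-weighted feature
#' indices in rank order. The subsequent per-tree feature subsets are drawn
#' from this restricted candidate space only.
#'
#' @param fw A `feature_weights` object.
#' @param beta Selection fraction in (0, 1].
#' @param n Number of features (defaults to all weighted features).
#' @return Integer vector of `n'` feature indices, highest weight first.
#' @export
rank_and_select <- function(fw, beta, n = length(fw$weights)) {
  stopifnot(inherits(fw, "feature_weights"))
  stop_if_not_scalar_number(beta, "beta")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  n_prime <- max(1L, as.integer(round(beta * n)))
  fw$order[seq_len(min(n_prime, length(fw$order)))]
}
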