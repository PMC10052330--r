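#' Forest configuration
#'
#' @param k Number of trees (default 50).
#' @param beta Fraction of the ranked feature space retained before per-tree
#'   subsampling, in (0, 1] (default 0.5).
#' @param t_override Per-tree feature-subset size; default
#'   `floor(log2(n')) + 1` via [default_t()].
#' @param seed Integer seed; the whole training run is reproducible from it.
#' @param tree A [tree_config()] for the base C4.5 trees.
#' @param bins Discretization bins for the chi-squared weighting.
#' @param per_node_sampling Draw the `t` features afresh at every node
#'   instead of once per tree (ablation mode; default `FALSE`, the
#'   per-tree draw).
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(k = 50L, beta = 0.5, t_override = NULL, seed = 1L,
                          tree = tree_config(), bins = 5L,
                          per_node_sampling = FALSE) {
  if (k < 1) stop("k must be >= 1")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (!is.null(t_override) && t_override < 1) stop("t_override must be >= 1")
  structure(
    list(k = as.integer(k), beta = beta,
         t_override = if (is.null(t_override)) NULL else as.integer(t_override),
         seed = as.integer(seed), tree = tree, bins = as.integer(bins),
         per_node_sampling = isTRUE(per_node_sampling)),
    class = "forest_config"
  )
}

#' Bootstrap sample of a dataset
#'
#' Draws N rows uniformly with replacement. The expected fraction of
#' distinct rows tends to `1 - 1/e ~ 0.632`; the rows left out of a draw
#' are the out-of-bag set used for the forest's internal error estimate.
#'
#' @param ds An [asv_dataset].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the forest trainer manages its own stream).
#' @return An [asv_dataset] of the drawn rows, with the drawn row indices
#'   in attribute `"indices"`.
#' @export
bootstrap_sample <- function(ds, seed = NULL) {
  stopifnot(inherits(ds, "asv_dataset"))
  N <- n_obs(ds)
  idx <- if (is.null(seed)) sample.int(N, N, replace = TRUE) else
    with_seed(seed, sample.int(N, N, replace = TRUE))
  out <- ds_subset(ds, idx)
  attr(out, "indices") <- idx
  out
}

#' Default per-tree feature-subset size
#'
#' `t = floor(log2(n')) + 1`, capped at `n'`, where `n'` is the number of
#' features surviving the top-`beta * n` selection.
#'
#' @param n_prime Number of selected features, >= 1.
#' @return Integer subset size.
#' @export
#' @examples
#' default_t(8)  # 4
#' default_t(5)  # 3
default_t <- function(n_prime) {
  if (n_prime < 1) stop("n_prime must be >= 1")
  min(as.integer(floor(log2(n_prime)) + 1), as.integer(n_prime))
}

#' Weight-biased feature subsampling
#'
#' Draws `t` distinct features sequentially without replacement, each draw
#' with probability proportional to the remaining features' chi-squared
#' weights. A small floor `eps` keeps zero-weight features selectable when
#' `t` approaches the pool size. With equal weights this reduces to uniform
#' sampling without replacement.
#'
#' @param weights Non-negative weights of the candidate pool.
#' @param t Number of features to draw, `t <= length(weights)`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param eps Additive weight floor (default 1e-12).
#' @return Integer indices into `weights`, in draw order.
#' @export
sample_features_weighted <- function(weights, t, seed = NULL, eps = 1e-12) {
  if (t > length(weights)) stop("t exceeds the number of candidate features")
  if (any(weights < 0)) stop("weights must be non-negative")
  p <- weights + eps
  if (is.null(seed)) sample.int(length(weights), t, replace = FALSE, prob = p)
  else with_seed(seed, sample.int(length(weights), t, replace = FALSE, prob = p))
}

#' Train the feature-weighted random forest
#'
#' The ensemble trainer: (1) scores every feature by chi-squared association
#' with the class label on the full training set, (2) ranks the features by
#' weight, (3) keeps the top `n' = max(1, round(beta * n))`, then (4) grows
#' `k` C4.5 trees, each on a fresh bootstrap sample of the rows with `t`
#' features drawn from the selected pool with probability proportional to
#' their weights. Prediction averages the trees' leaf probabilities
#' ([forest_predict_proba()]). Out-of-bag accuracy is estimated as a
#' by-product. The full run is deterministic given `cfg$seed`.
#'
#' @param train An [asv_dataset] without missing values, with at least two
#'   classes present.
#' @param cfg A [forest_config()].
#' @return An object of class `asv_forest`: `trees`, `feature_subsets`
#'   (global column indices per tree), `selected` (the top-`n'` pool),
#'   `weights` (the `feature_weights` object), `tree_seeds`, `config`,
#'   `class_names`, `feature_names`, `oob_accuracy`.
#' @export
#' @examples
#' ds <- asv_dataset(matrix(rnorm(200), 50, 4),
#'                   rep(c("a", "b"), 25))
#' f <- train_asv_rf(ds, forest_config(k = 5, seed = 42))
#' table(forest_predict(f, ds))
train_asv_rf <- function(train, cfg = forest_config()) {
  stopifnot(inherits(train, "asv_dataset"), inherits(cfg, "forest_config"))
  if (anyNA(train$features)) stop("missing values present; impute first")
  if (length(unique(train$labels)) < 2) {
    stop("training data contain a single class; nothing to learn")
  }
  N <- n_obs(train)
  n <- n_features(train)
  a <- n_classes(train)
  fw <- compute_feature_weights(train, bins = cfg$bins)          # stage 1-2
  selected <- rank_and_select(fw, cfg$beta, n)                   # stage 3
  n_prime <- length(selected)
  t_size <- min(cfg$t_override %||% default_t(n_prime), n_prime)
  w_sel <- fw$weights[selected]

  tree_seeds <- with_seed(cfg$seed,
                          sample.int(.Machine$integer.max - 1L, cfg$k))
  trees <- vector("list", cfg$k)
  subsets <- vector("list", cfg$k)
  votes <- matrix(0, N, a)
  oob_n <- integer(N)
  for (i in seq_len(cfg$k)) {                                    # stage 4
    with_seed(tree_seeds[i], {
      bidx <- sample.int(N, N, replace = TRUE)
      feats <- selected[sample_features_weighted(w_sel, t_size)]
      sampler <- if (cfg$per_node_sampling) {
        function() selected[sample_features_weighted(w_sel, t_size)]
      }
      trees[[i]] <- build_tree(train$features[bidx, , drop = FALSE],
                               train$labels[bidx],
                               candidate_features = feats,
                               cfg = cfg$tree, n_class = a,
                               feature_sampler = sampler)
    })
    subsets[[i]] <- feats
    oob <- setdiff(seq_len(N), bidx)
    if (length(oob)) {
      votes[oob, ] <- votes[oob, ] +
        tree_predict_matrix(trees[[i]], train$features[oob, , drop = FALSE], a)
      oob_n[oob] <- oob_n[oob] + 1L
    }
  }
  covered <- oob_n > 0
  oob_acc <- if (any(covered)) {
    pred <- max.col(votes[covered, , drop = FALSE], ties.method = "first")
    mean(pred == train$labels[covered])
  } else NA_real_
  structure(
    list(trees = trees, feature_subsets = subsets, selected = selected,
         t = t_size, weights = fw, tree_seeds = tree_seeds, config = cfg,
         class_names = train$class_names, feature_names = train$feature_names,
         oob_accuracy = oob_acc),
    class = "asv_forest"
  )
}

#' @export
print.asv_forest <- function(x, ...) {
  cat(sprintf(
    "asv_forest: %d C4.5 trees, %d/%d features selected (beta = %g), t = %d%s\n",
    length(x$trees), length(x$selected), length(x$weights$weights),
    x$config$beta, x$t,
    if (is.na(x$oob_accuracy)) "" else sprintf(", OOB accuracy %.3f", x$oob_accuracy)
  ))
  invisible(x)
}

as_feature_matrix <- function(forest, newdata) {
  X <- if (inherits(newdata, "asv_dataset")) newdata$features else
    as.matrix(newdata)
  if (ncol(X) != length(forest$feature_names)) {
    stop(sprintf("newdata has %d features but the forest expects %d",
                 ncol(X), length(forest$feature_names)))
  }
  if (anyNA(X)) stop("missing values present; apply the preprocessor first")
  X
}

#' Ensemble class probabilities by probability averaging
#'
#' The soft vote: `P(c_i | x) = (1/k) sum_j P(c_i | x, h_j)` over the k
#' trees, a convex combination of the trees' leaf distributions, so the
#' output always lies on the probability simplex.
#'
#' @param forest An `asv_forest`.
#' @param newdata An [asv_dataset] or numeric matrix in the training
#'   feature space.
#' @return N x a matrix of class probabilities (columns named by class).
#' @export
forest_predict_proba <- function(forest, newdata) {
  stopifnot(inherits(forest, "asv_forest"))
  if (!length(forest$trees)) stop("empty forest")
  X <- as_feature_matrix(forest, newdata)
  a <- length(forest$class_names)
  P <- matrix(0, nrow(X), a)
  for (tr in forest$trees) P <- P + tree_predict_matrix(tr, X, a)
  P <- P / length(forest$trees)
  colnames(P) <- forest$class_names
  P
}

#' Ensemble label prediction
#'
#' Argmax of the averaged probabilities; ties go to the lowest class index
#' (first-seen class), which keeps prediction deterministic.
#'
#' @inheritParams forest_predict_proba
#' @return Character vector of predicted class names.
#' @export
forest_predict <- function(forest, newdata) {
  P <- forest_predict_proba(forest, newdata)
  forest$class_names[max.col(P, ties.method = "first")]
}
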