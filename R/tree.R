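#' Shannon entropy of a label vector
#'
#' `-sum p_i log2 p_i` in bits, with `0 log 0 = 0`. A pure vector has
#' entropy 0; a balanced binary vector has exactly 1 bit.
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c("a", "a", "b", "b"))
entropy <- function(labels) {
  if (!length(labels)) stop("entropy of an empty vector is undefined")
  entropy_counts(as.numeric(table(labels)))
}

entropy_counts <- function(counts) {
  tot <- sum(counts)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# entropy of each row of a count matrix, given row totals
row_entropy <- function(counts, totals) {
  p <- counts / totals
  terms <- p * log2(p)
  terms[counts == 0] <- 0
  -rowSums(terms)
}

#' Configuration of a single decision tree
#'
#' @param min_samples_leaf Minimum rows per leaf (default 1); a node with
#'   fewer than `2 * min_samples_leaf` rows becomes a leaf, and candidate
#'   thresholds must leave at least `min_samples_leaf` rows on each side.
#' @param max_depth Depth limit (default `Inf` = unlimited; the trees are
#'   grown unpruned, which is the conventional low-bias choice inside an
#'   ensemble).
#' @param min_gain_ratio Minimum admissible gain ratio for a split
#'   (default 0; independently of this, a split's information gain must be
#'   strictly positive).
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(min_samples_leaf = 1L, max_depth = Inf,
                        min_gain_ratio = 0) {
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1")
  if (max_depth < 1) stop("max_depth must be >= 1 (or Inf)")
  structure(
    list(min_samples_leaf = as.integer(min_samples_leaf),
         max_depth = max_depth, min_gain_ratio = min_gain_ratio),
    class = "tree_config"
  )
}

#' Best gain-ratio split over candidate features
#'
#' Scans, for each candidate feature, every midpoint between consecutive
#' distinct sorted values, and returns the (feature, threshold) maximizing
#' the C4.5 gain ratio: information gain divided by the entropy of the
#' binary partition. Splits with non-positive information gain are never
#' admissible (the C4.5 guard), and `min_gain_ratio` can raise the bar
#' further. Ties (within 1e-12) are broken by lower feature index, then
#' lower threshold. Returns `NULL` when no admissible split exists, e.g.
#' for pure labels or all-constant candidate features.
#'
#' @param features Numeric matrix of the node's rows (all columns present;
#'   only `candidate_features` are scanned).
#' @param labels Integer class codes `1..n_class` for the node's rows.
#' @param candidate_features Integer column indices to scan.
#' @param cfg A [tree_config()].
#' @param n_class Total number of classes (defaults to `max(labels)`).
#' @return `NULL`, or a list `feature`, `threshold`, `gain_ratio`, `gain`.
#' @export
best_split <- function(features, labels, candidate_features = seq_len(ncol(features)),
                       cfg = tree_config(), n_class = max(labels)) {
  if (!length(candidate_features)) stop("candidate feature list is empty")
  n <- length(labels)
  if (n < 2) return(NULL)
  counts <- tabulate(labels, n_class)
  base_ent <- entropy_counts(counts)
  msl <- cfg$min_samples_leaf
  best <- NULL
  best_gr <- -Inf
  for (f in sort(unique(as.integer(candidate_features)))) {
    x <- features[, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    ys <- labels[o]
    cuts <- which(xs[-n] < xs[-1])  # left part sizes at admissible cuts
    cuts <- cuts[cuts >= msl & (n - cuts) >= msl]
    if (!length(cuts)) next
    ind <- matrix(0, n, n_class)
    ind[cbind(seq_len(n), ys)] <- 1
    cum <- apply(ind, 2, cumsum)
    Lc <- cum[cuts, , drop = FALSE]
    nl <- cuts
    nr <- n - nl
    Rc <- matrix(counts, length(cuts), n_class, byrow = TRUE) - Lc
    gain <- base_ent - (nl * row_entropy(Lc, nl) + nr * row_entropy(Rc, nr)) / n
    pl <- nl / n
    split_info <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
    gr <- gain / split_info
    ok <- gain > 1e-12 & gr >= cfg$min_gain_ratio
    if (!any(ok)) next
    gr[!ok] <- -Inf
    m <- max(gr)
    j <- which(gr >= m - 1e-12)[1]  # lowest threshold among ties
    if (gr[j] > best_gr + 1e-12) {
      best_gr <- gr[j]
      best <- list(feature = f,
                   threshold = (xs[cuts[j]] + xs[cuts[j] + 1]) / 2,
                   gain_ratio = gr[j], gain = gain[j])
    }
  }
  best
}

laplace_leaf <- function(counts) {
  n <- sum(counts)
  list(type = "leaf", prob = (counts + 1) / (n + length(counts)),
       n = as.integer(n))
}

#' Grow a C4.5-style decision tree
#'
#' Recursive induction with binary threshold splits chosen by
#' [best_split()]. A node becomes a leaf when it is pure, has fewer than
#' `2 * min_samples_leaf` rows, hits the depth limit, or admits no split
#' with positive gain. Leaf class probabilities are Laplace-smoothed
#' frequencies `(count_i + 1) / (n + a)`, which keeps every class strictly
#' positive probability and makes probability averaging across the ensemble
#' well behaved. Induction is deterministic given identical inputs unless a
#' `feature_sampler` is supplied (per-node random subspacing).
#'
#' @param features Numeric matrix (training rows; global column indexing).
#' @param labels Integer class codes `1..n_class`.
#' @param candidate_features Columns the tree may split on.
#' @param cfg A [tree_config()].
#' @param n_class Total number of classes.
#' @param feature_sampler Optional function returning the candidate columns
#'   for one node (used by the forest's per-node sampling mode); draws from
#'   the current RNG stream.
#' @return The root `TreeNode`: nested lists, internal nodes
#'   `list(type = "split", feature, threshold, left, right)`, leaves
#'   `list(type = "leaf", prob, n)`.
#' @export
build_tree <- function(features, labels, candidate_features = seq_len(ncol(features)),
                       cfg = tree_config(), n_class = max(labels),
                       feature_sampler = NULL) {
  if (!length(labels)) stop("empty training set")
  grow <- function(idx, depth) {
    counts <- tabulate(labels[idx], n_class)
    if (sum(counts > 0) <= 1 ||
        length(idx) < 2 * cfg$min_samples_leaf ||
        depth >= cfg$max_depth) {
      return(laplace_leaf(counts))
    }
    cand <- if (is.null(feature_sampler)) candidate_features else feature_sampler()
    sp <- best_split(features[idx, , drop = FALSE], labels[idx],
                     candidate_features = cand, cfg = cfg, n_class = n_class)
    if (is.null(sp)) return(laplace_leaf(counts))
    go_left <- features[idx, sp$feature] <= sp$threshold
    list(type = "split", feature = sp$feature, threshold = sp$threshold,
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }
  grow(seq_along(labels), 0L)
}

#' Class probabilities of one tree for one observation
#'
#' Routes `x` down the tree (values `<= threshold` go left, including values
#' exactly at the threshold) and returns the reached leaf's probability
#' vector.
#'
#' @param tree A tree from [build_tree()].
#' @param x Numeric feature vector (full feature space of the training
#'   matrix; the tree only inspects its own split features).
#' @return Probability vector over the classes.
#' @export
tree_predict_proba <- function(tree, x) {
  node <- tree
  while (node$type == "split") {
    if (node$feature > length(x)) stop("feature vector shorter than the tree expects")
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prob
}

# vectorized prediction: recursively partition row indices down the tree
tree_predict_matrix <- function(tree, X, n_class) {
  P <- matrix(NA_real_, nrow(X), n_class)
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (node$type == "leaf") {
      P[idx, ] <<- matrix(node$prob, length(idx), n_class, byrow = TRUE)
      return(invisible(NULL))
    }
    le <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[le])
    rec(node$right, idx[!le])
  }
  rec(tree, seq_len(nrow(X)))
  P
}
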