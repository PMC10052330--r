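test_that("entropy matches direct formula evaluation", {
  expect_equal(entropy(rep("a", 7)), 0)
  expect_equal(entropy(c("a", "a", "b", "b")), 1)
  expect_equal(entropy(c("a", "a", "a", "b")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(entropy(character(0)), "empty")
})

test_that("best_split finds the separating midpoint with gain ratio 1", {
  X <- matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1)
  y <- c(1L, 1L, 2L, 2L)
  sp <- best_split(X, y)
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 0.5)
  expect_equal(sp$gain_ratio, 1)
})

test_that("best_split refuses pure labels, constant features, empty candidates", {
  X <- cbind(c(0.1, 0.2, 0.8, 0.9), rep(0.5, 4))
  expect_null(best_split(X, rep(1L, 4), n_class = 2))
  # constant feature never chosen even when listed
  sp <- best_split(X, c(1L, 1L, 2L, 2L), candidate_features = 1:2)
  expect_equal(sp$feature, 1)
  expect_null(best_split(X[, 2, drop = FALSE], c(1L, 1L, 2L, 2L)))
  expect_error(best_split(X, c(1L, 1L, 2L, 2L), candidate_features = integer(0)),
               "empty")
})

test_that("best_split agrees with exhaustive brute force on random small data", {
  set.seed(207)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(sample(seq(0, 1, 0.05), n * p, TRUE), n, p)
    y <- sample.int(sample(2:3, 1), n, TRUE)
    sp <- best_split(X, y, n_class = max(y))
    or <- oracle_best_split(X, y)
    if (is.null(or)) {
      expect_null(sp)
    } else {
      expect_equal(sp$feature, or$feature)
      expect_equal(sp$threshold, or$threshold)
      expect_equal(sp$gain_ratio, or$gain_ratio, tolerance = 1e-9)
    }
  }
})

test_that("min_samples_leaf restricts admissible cuts", {
  X <- matrix(c(0.1, 0.2, 0.3, 0.9), 4, 1)
  y <- c(1L, 2L, 2L, 2L)
  sp <- best_split(X, y, cfg = tree_config(min_samples_leaf = 2))
  expect_equal(sp$threshold, 0.25)  # the 1-vs-3 cut is no longer admissible
})

test_that("tree induction stops correctly and routes by the <= convention", {
  # pure input -> single Laplace-shrunk leaf
  tr <- build_tree(matrix(runif(5), 5, 1), rep(1L, 5), n_class = 2)
  expect_equal(tr$type, "leaf")
  expect_equal(tr$prob, c(6, 1) / 7)

  # the 4-point dataset grows one split and two pure leaves
  X <- matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1)
  tr <- build_tree(X, c(1L, 1L, 2L, 2L), n_class = 2)
  expect_equal(tr$type, "split")
  expect_equal(tr$left$type, "leaf")
  expect_equal(tr$right$type, "leaf")
  expect_equal(tree_predict_proba(tr, 0.15), c(3, 1) / 4)
  expect_equal(tree_predict_proba(tr, 0.85), c(1, 3) / 4)
  # boundary value goes left
  expect_equal(tree_predict_proba(tr, tr$threshold),
               tree_predict_proba(tr, tr$threshold - 1e-9))
})

test_that("depth limits terminate induction on threshold-inseparable labels", {
  X <- matrix(c(0, 1, 0, 1, 0.5, 0.5, 0.5, 0.5), 4, 2)
  y <- c(1L, 2L, 2L, 1L)  # conflicting labels at duplicate x values
  tr <- build_tree(X, y, cfg = tree_config(max_depth = 3), n_class = 2)
  depth_of <- function(node) {
    if (node$type == "leaf") 0 else 1 + max(depth_of(node$left),
                                            depth_of(node$right))
  }
  expect_lte(depth_of(tr), 3)
  expect_error(build_tree(X[0, , drop = FALSE], integer(0)), "empty")
})

test_that("unlimited trees memorize conflict-free training data", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 40
    X <- matrix(runif(n * 3), n, 3)
    y <- sample.int(2, n, TRUE)
    tr <- build_tree(X, y, n_class = 2)
    pred <- apply(X, 1, function(x) which.max(tree_predict_proba(tr, x)))
    expect_equal(unname(pred), y)
  }
})

test_that("tree building is deterministic for identical inputs", {
  set.seed(23)
  X <- matrix(runif(120), 40, 3)
  y <- sample.int(2, 40, TRUE)
  expect_identical(build_tree(X, y, n_class = 2), build_tree(X, y, n_class = 2))
})
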