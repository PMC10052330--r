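test_that("scatter matrices match the brute-force outer-product definitions", {
  X <- matrix(c(0.1, 0.4, 0.9, 0.2, 0.8, 0.7,
                0.3, 0.5, 0.6, 0.9, 0.1, 0.2), 6, 2)
  y <- c("a", "a", "a", "b", "b", "b")
  ds <- asv_dataset(X, y)
  sc <- scatter_matrices(ds)
  o <- oracle_scatter(X, y)
  expect_equal(sc$S_C, o$S_C, tolerance = 1e-12)
  expect_equal(sc$S_V, o$S_V, tolerance = 1e-12)
  expect_equal(sc$S_C, t(sc$S_C))
  expect_equal(sc$S_V, t(sc$S_V))
})

test_that("degenerate scatter cases: equal means and singleton classes", {
  # identical class means -> zero between-class scatter
  X <- rbind(c(0, 1), c(2, 3), c(2, 3), c(0, 1))
  ds <- asv_dataset(X, c("a", "a", "b", "b"))
  expect_equal(scatter_matrices(ds)$S_C, matrix(0, 2, 2))
  # one point per class -> zero within-class scatter
  ds1 <- asv_dataset(rbind(c(0, 1), c(5, 2)), c("a", "b"))
  expect_equal(scatter_matrices(ds1)$S_V, matrix(0, 2, 2))
  # preconditions
  ds_na <- asv_dataset(matrix(c(1, NA, 3, 4), 2, 2), c("a", "b"))
  expect_error(scatter_matrices(ds_na), "missing")
  ds_empty <- asv_dataset(matrix(1:4, 2, 2), c("a", "a"),
                          class_names = c("a", "b"))
  expect_error(scatter_matrices(ds_empty), "no members")
})

test_that("between plus within scatter equals total scatter", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(c("a", "b", "c"), 40, TRUE)
    ds <- asv_dataset(X, y)
    sc <- scatter_matrices(ds)
    total <- crossprod(sweep(X, 2, colMeans(X)))
    expect_equal(sc$S_C + sc$S_V, total, tolerance = 1e-9)
  }
})

test_that("leading discriminant recovers the closed-form Fisher direction", {
  set.seed(42)
  n <- 250
  p <- 5
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) / p + diag(p)
  R <- chol(Sigma)
  mu1 <- rep(0, p)
  mu2 <- c(2, 1, -1, 0.5, 0)
  X <- rbind(matrix(rnorm(n * p), n) %*% R,
             sweep(matrix(rnorm(n * p), n) %*% R, 2, mu2, `+`))
  ds <- asv_dataset(X, rep(c("a", "b"), each = n))
  m <- fit_lda(ds, L = 1)
  fisher <- solve(Sigma, mu2 - mu1)
  cosine <- abs(sum(m$W[, 1] * fisher)) /
    sqrt(sum(m$W[, 1]^2) * sum(fisher^2))
  expect_gte(cosine, 0.99)
  expect_equal(sqrt(sum(m$W[, 1]^2)), 1, tolerance = 1e-12)
  # at most a - 1 strictly positive eigenvalues
  m_full <- fit_lda(ds, L = 1)
  expect_lte(sum(m_full$eigenvalues > 1e-6), n_classes(ds) - 1)
})

test_that("subspace dimension limits and sign convention are enforced", {
  ds <- separable_dataset(n_per_class = 20, n_features = 3)
  expect_error(fit_lda(ds, L = 2), "L must lie")  # a = 2 caps L at 1
  m <- fit_lda(ds, L = 1)
  expect_gt(m$W[which.max(abs(m$W[, 1])), 1], 0)
  # 1-D two-class problem: the only unit direction
  ds1 <- toy_dataset(c(0.1, 0.2, 3.4, 3.9), labels = c("a", "a", "b", "b"))
  expect_equal(fit_lda(ds1, L = 1)$W, matrix(1, 1, 1))
})

test_that("projection is W^T x with labels carried through", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  ds <- asv_dataset(X, c("a", "b", "a"))
  m <- fit_lda(separable_dataset(n_features = 2), L = 1)
  m$W <- matrix(c(0.6, 0.8), 2, 1)  # fixed basis, hand-multiplied oracle
  out <- lda_project(m, ds)
  expect_equal(out$features, X %*% m$W)
  expect_equal(label_names(out), c("a", "b", "a"))
  expect_error(lda_project(m, separable_dataset(n_features = 3)), "features")
})

test_that("training projections order the classes along the leading axis", {
  ds <- separable_dataset(n_per_class = 30, n_features = 2, shift = 5)
  m <- fit_lda(ds, L = 1)
  z <- lda_project(m, ds)$features[, 1]
  expect_true(max(z[ds$labels == 1]) < min(z[ds$labels == 2]) ||
                min(z[ds$labels == 1]) > max(z[ds$labels == 2]))
})
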