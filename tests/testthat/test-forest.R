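test_that("default feature-subset size follows floor(log2 n') + 1 with cap", {
  expect_equal(default_t(8), 4)
  expect_equal(default_t(5), 3)
  expect_equal(default_t(1), 1)
  expect_equal(default_t(2), 2)
  expect_error(default_t(0), ">= 1")
})

test_that("bootstrap sampling is seeded and covers ~63% distinct rows", {
  ds <- separable_dataset(n_per_class = 500, n_features = 2)
  b1 <- bootstrap_sample(ds, seed = 9)
  b2 <- bootstrap_sample(ds, seed = 9)
  expect_identical(attr(b1, "indices"), attr(b2, "indices"))
  expect_equal(n_obs(b1), n_obs(ds))
  set.seed(2)
  fracs <- replicate(30, length(unique(attr(bootstrap_sample(ds), "indices"))) /
                       n_obs(ds))
  expect_lt(abs(mean(fracs) - (1 - exp(-1))), 0.02)

  one <- asv_dataset(matrix(1:2, 1, 2), "a")
  expect_equal(n_obs(bootstrap_sample(one, seed = 1)), 1)
})

test_that("weighted feature sampling honors weights and exhausts the pool", {
  set.seed(6)
  hits <- replicate(1000, sample_features_weighted(c(1e6, 1, 1, 1), 1)) == 1
  expect_gte(mean(hits), 0.99)
  expect_setequal(sample_features_weighted(c(2, 3, 4), 3), 1:3)
  expect_error(sample_features_weighted(c(1, 2), 3), "exceeds")
  expect_error(sample_features_weighted(c(-1, 2), 1), "non-negative")
  # zero weights stay selectable through the floor
  expect_setequal(sample_features_weighted(c(0, 0, 5), 3), 1:3)
})

test_that("uniform weights reduce to uniform sampling without replacement", {
  set.seed(41)
  draws <- replicate(10000, sample_features_weighted(rep(1, 5), 2))
  incl <- tabulate(as.vector(draws), 5)
  # chi-squared goodness of fit against equal inclusion, alpha = 0.01
  gof <- sum((incl - mean(incl))^2 / mean(incl))
  expect_lt(gof, qchisq(0.99, df = 4))
})

test_that("training is seeded-deterministic and respects the selected pool", {
  co <- generate_cohort(cohort_spec(n_patients = 10, readings_per_patient = 10,
                                    missing_rate = 0, seed = 8))
  cfg <- forest_config(k = 8, beta = 0.5, seed = 12)
  f1 <- train_asv_rf(co$dataset, cfg)
  f2 <- train_asv_rf(co$dataset, cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$feature_subsets, f2$feature_subsets)
  n_prime <- length(f1$selected)
  expect_equal(n_prime, round(0.5 * n_features(co$dataset)))
  for (s in f1$feature_subsets) {
    expect_length(s, f1$t)
    expect_length(unique(s), f1$t)
    expect_true(all(s %in% f1$selected))
  }
  expect_equal(f1$t, default_t(n_prime))
  expect_error(train_asv_rf(asv_dataset(matrix(1:4, 2, 2), c("a", "a")), cfg),
               "single class")
})

test_that("a k = 1, beta = 1, t = n forest degenerates to one plain tree", {
  ds <- separable_dataset(n_per_class = 20, n_features = 3)
  cfg <- forest_config(k = 1, beta = 1, t_override = 3, seed = 5)
  f <- train_asv_rf(ds, cfg)
  # rebuild the single tree by replaying the seeded bootstrap
  seed1 <- with_seed(5, sample.int(.Machine$integer.max - 1L, 1))
  tr <- with_seed(seed1, {
    bidx <- sample.int(40, 40, replace = TRUE)
    sample_features_weighted(f$weights$weights[f$selected], 3)
    build_tree(ds$features[bidx, , drop = FALSE], ds$labels[bidx],
               candidate_features = f$feature_subsets[[1]], n_class = 2)
  })
  expect_identical(f$trees[[1]], tr)
  X <- matrix(runif(30), 10, 3)
  expect_equal(forest_predict_proba(f, X)[3, ],
               tree_predict_proba(tr, X[3, ]), ignore_attr = TRUE)
})

test_that("probability averaging is the arithmetic mean over trees", {
  leafs <- function(p) list(type = "leaf", prob = p, n = 10L)
  f <- structure(
    list(trees = list(leafs(c(0.8, 0.2)), leafs(c(0.4, 0.6))),
         feature_subsets = list(1L, 1L), selected = 1L, t = 1L,
         weights = NULL, tree_seeds = c(1L, 2L),
         config = forest_config(k = 2), class_names = c("c1", "c2"),
         feature_names = "f1", oob_accuracy = NA_real_),
    class = "asv_forest")
  P <- forest_predict_proba(f, matrix(0.5, 1, 1))
  expect_equal(unname(P[1, ]), c(0.6, 0.4))
  expect_equal(forest_predict(f, matrix(0.5, 1, 1)), "c1")
  f$trees <- list()
  expect_error(forest_predict_proba(f, matrix(0.5, 1, 1)), "empty forest")
})

test_that("ensemble output is a simplex point bounded by the tree outputs", {
  ds <- separable_dataset(n_per_class = 30, n_features = 4, shift = 1)
  f <- train_asv_rf(ds, forest_config(k = 10, seed = 3))
  X <- matrix(rnorm(200), 50, 4)
  P <- forest_predict_proba(f, X)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-9)
  per_tree <- sapply(f$trees, function(tr)
    tree_predict_proba(tr, X[1, ])[1])
  expect_gte(P[1, 1], min(per_tree) - 1e-12)
  expect_lte(P[1, 1], max(per_tree) + 1e-12)
})

test_that("out-of-bag accuracy is reported for reasonably sized data", {
  ds <- separable_dataset(n_per_class = 25, n_features = 3)
  f <- train_asv_rf(ds, forest_config(k = 10, seed = 2))
  expect_true(is.finite(f$oob_accuracy))
  expect_gte(f$oob_accuracy, 0.8)  # trivially separable classes
})

test_that("per-node subsampling mode trains and predicts", {
  ds <- separable_dataset(n_per_class = 20, n_features = 4)
  f <- train_asv_rf(ds, forest_config(k = 4, seed = 11,
                                      per_node_sampling = TRUE))
  expect_length(f$trees, 4)
  expect_true(all(forest_predict(f, ds) %in% c("a", "b")))
})
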