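test_that("dataset constructor validates and encodes labels in first-seen order", {
  ds <- asv_dataset(matrix(1:6, 3, 2), c("b", "a", "b"))
  expect_equal(ds$class_names, c("b", "a"))
  expect_equal(ds$labels, c(1L, 2L, 1L))
  expect_equal(label_names(ds), c("b", "a", "b"))
  expect_error(asv_dataset(matrix(1:4, 2, 2), c("a", "b"),
                           feature_names = c("x", "x")),
               "unique")
  expect_error(asv_dataset(matrix(1:4, 2, 2), c("a", "b"),
                           class_names = "a"),
               "not listed")
})

test_that("CSV read parses values, missing tokens and errors on bad input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,label", "1,2,x", "3,NA,y", "5,6,x", "7,8,y"), p)
  ds <- read_csv_dataset(p, "label")
  expect_equal(n_obs(ds), 4)
  expect_equal(n_features(ds), 2)
  expect_equal(n_classes(ds), 2)
  expect_true(is.na(ds$features[2, 2]))
  expect_equal(ds$features[, 1], c(1, 3, 5, 7))
  expect_error(read_csv_dataset(p, "outcome"), "label column")
  expect_error(read_csv_dataset(file.path(tempdir(), "nope.csv"), "label"),
               "not found")

  writeLines(c("g1,label", "oops,x", "2,y"), p)
  expect_error(read_csv_dataset(p, "label"), "non-numeric")
  writeLines("g1,label", p)
  expect_error(read_csv_dataset(p, "label"), "no data rows")
})

test_that("CSV read -> write -> read is a fixed point including missingness", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  X[sample(60, 10)] <- NA
  ds <- asv_dataset(X, sample(c("a", "b"), 20, TRUE))
  p <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, p)
  ds2 <- read_csv_dataset(p, "label")
  expect_identical(ds2$features, ds$features)
  expect_identical(ds2$labels, ds$labels)
  expect_identical(ds2$feature_names, ds$feature_names)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("split is seeded, partitioning, and stratification preserves proportions", {
  set.seed(4)
  ds <- asv_dataset(matrix(rnorm(200), 100, 2),
                    rep(c("a", "b"), c(60, 40)))
  s1 <- split_dataset(ds, 0.2, seed = 7)
  s2 <- split_dataset(ds, 0.2, seed = 7)
  expect_identical(s1$test_idx, s2$test_idx)
  expect_equal(n_obs(s1$test) + n_obs(s1$train), 100)
  expect_length(intersect(s1$test_idx, setdiff(1:100, s1$test_idx)), 0)
  # per-class test counts within 1 of test_fraction * class size
  tab <- table(label_names(s1$test))
  expect_lt(abs(tab[["a"]] - 0.2 * 60), 1)
  expect_lt(abs(tab[["b"]] - 0.2 * 40), 1)

  ds10 <- asv_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  s <- split_dataset(ds10, 0.2, seed = 1)
  expect_equal(as.vector(table(label_names(s$test))), c(1, 1))

  expect_error(split_dataset(ds, 1.0, seed = 1), "strictly inside")
  expect_error(split_dataset(ds, 0, seed = 1), "strictly inside")
  ds_bad <- asv_dataset(matrix(rnorm(6), 3, 2), c("a", "a", "b"))
  expect_error(split_dataset(ds_bad, 0.3, seed = 1), "fewer than 2")
})

test_that("model bundles round-trip through JSON with bit-identical predictions", {
  co <- generate_cohort(cohort_spec(n_patients = 10, readings_per_patient = 10,
                                    seed = 21))
  bundle <- suppressMessages(
    run_train(pipeline_config(seed = 3, k = 4, lda = TRUE), co$dataset))
  p <- withr::local_tempfile(fileext = ".json")
  save_model(bundle, p)
  loaded <- load_model(p)
  expect_identical(predict_model(loaded, co$dataset)$proba,
                   predict_model(bundle, co$dataset)$proba)
  expect_identical(loaded$normalizer, bundle$normalizer)
  expect_equal(loaded$forest$trees, bundle$forest$trees)

  # truncated file is rejected
  txt <- readLines(p)
  p_bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), p_bad)
  expect_error(load_model(p_bad), "corrupt")

  # an emptied forest is rejected at save time
  bundle$forest$trees <- list()
  expect_error(save_model(bundle, p), "empty forest")
})
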