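test_that("confusion counts match a manual tally", {
  y_true <- c("p", "p", "p", "n", "n", "n", "p", "n", "p", "n")
  y_pred <- c("p", "n", "p", "n", "p", "n", "p", "n", "p", "p")
  cm <- confusion(y_true, y_pred, "p")
  expect_equal(cm$tp, 4)
  expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 2)
  expect_equal(cm$tn, 3)
  expect_error(confusion(y_true, y_pred[1:5], "p"), "same length")
  expect_error(confusion(y_true, y_pred, NA_character_), "positive class")

  perfect <- confusion(y_true, y_true, "p")
  expect_equal(perfect$fp + perfect$fn, 0)
  all_pos <- confusion(y_true, rep("p", 10), "p")
  expect_equal(all_pos$tn, 0)
  expect_equal(all_pos$fp, 5)
})

test_that("rates match direct arithmetic on a hand-built matrix", {
  cm <- structure(list(tp = 50, fp = 10, tn = 30, fn = 10, positive = "p",
                       table = NULL), class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$sensitivity, 50 / 60)
  expect_equal(m$specificity, 0.75)
  expect_identical(m$sensitivity, m$recall)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 60) / (50 / 60 + 50 / 60))
  expect_equal(m$proper_classified + m$improper_classified, 1)
  # F1 identity: F1 (p + r) = 2 p r
  expect_equal(m$f1 * (m$precision + m$recall),
               2 * m$precision * m$recall, tolerance = 1e-12)
})

test_that("a perfect classifier scores 1 everywhere including kappa", {
  m <- compute_metrics(confusion(rep(c("p", "n"), 10), rep(c("p", "n"), 10), "p"))
  for (f in c("accuracy", "precision", "sensitivity", "recall",
              "specificity", "f1", "kappa")) {
    expect_equal(m[[f]], 1)
  }
})

test_that("kappa is near zero for label-independent predictions", {
  set.seed(101)
  y <- sample(c("p", "n"), 10000, TRUE, prob = c(0.6, 0.4))
  yhat <- sample(c("p", "n"), 10000, TRUE, prob = c(0.3, 0.7))
  m <- compute_metrics(confusion(y, yhat, "p"))
  expect_lt(abs(m$kappa), 0.05)
})

test_that("zero denominators warn and report 0 instead of aborting", {
  cm <- confusion(rep("n", 5), rep("n", 5), "p")  # no positives anywhere
  expect_warning(m <- compute_metrics(cm), "zero-denominator")
  expect_equal(m$precision, 0)
  expect_equal(m$sensitivity, 0)
  expect_true(all(c("precision", "sensitivity") %in% m$undefined))
  expect_equal(m$accuracy, 1)
})

test_that("probability errors follow the MAE/RMSE definitions", {
  expect_equal(mae_rmse(c(1, 0), c(1, 0)), list(mae = 0, rmse = 0))
  expect_equal(mae_rmse(rep(c(1, 0), 5), rep(0.5, 10)),
               list(mae = 0.5, rmse = 0.5))
  pe <- mae_rmse(c(1, 0, 1), c(0.9, 0.2, 0.6))
  expect_equal(pe$mae, (0.1 + 0.2 + 0.4) / 3)
  expect_equal(pe$rmse, sqrt((0.01 + 0.04 + 0.16) / 3))
  expect_error(mae_rmse(c(1, 0), 0.5), "same length")
  expect_error(mae_rmse(c(1, 0), c(0.5, 1.2)), "0, 1")
})

test_that("report tables format percentages and round-trip through JSON", {
  m <- compute_metrics(confusion(rep(c("p", "n"), c(6, 4)),
                                 rep(c("p", "n"), c(5, 5)), "p"))
  out <- report_tables(list(model_a = m, model_b = m))
  expect_true(any(grepl("model_a", out$text)))
  expect_true(any(grepl("%", out$text)))
  parsed <- jsonlite::fromJSON(out$json)
  expect_equal(parsed$model_a$accuracy, m$accuracy)
  expect_equal(parsed$model_b$kappa, m$kappa)
  # percent formatting
  expect_true(any(grepl("99.86%", report_tables(local({
    cm <- structure(list(tp = 9986, fp = 14, tn = 0, fn = 0, positive = "p",
                         table = NULL), class = "confusion_matrix")
    suppressWarnings(compute_metrics(cm))
  }))$text)))
})
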