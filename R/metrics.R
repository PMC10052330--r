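#' Binary confusion matrix with respect to a positive class
#'
#' Standard 2 x 2 cross-tabulation of truth against prediction: TP (true
#' positive), FP (false positive), TN, FN, counted one-vs-rest when more
#' than two classes are present. The full a x a count table is kept
#' alongside.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class The class counted as positive; must occur among
#'   the classes of `y_true` or `y_pred`.
#' @return An object of class `confusion_matrix`: `tp`, `fp`, `tn`, `fn`,
#'   `positive`, `table`.
#' @export
#' @examples
#' confusion(c("p", "p", "n"), c("p", "n", "n"), "p")
confusion <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!is.character(positive_class) || length(positive_class) != 1 ||
      is.na(positive_class)) {
    stop("positive class must be a single class name")
  }
  # the declared positive class joins the vocabulary even when absent from a
  # degenerate evaluation set (e.g. a tiny CV fold with no positives)
  classes <- union(union(unique(y_true), unique(y_pred)), positive_class)
  tpos <- y_true == positive_class
  ppos <- y_pred == positive_class
  structure(
    list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
         tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos),
         positive = positive_class,
         table = table(truth = factor(y_true, classes),
                       prediction = factor(y_pred, classes))),
    class = "confusion_matrix"
  )
}

safe_ratio <- function(num, den, name, undefined) {
  if (den == 0) {
    undefined$flags <- c(undefined$flags, name)
    0
  } else num / den
}

#' Evaluation metrics from a confusion matrix
#'
#' Computes the rate suite: accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, sensitivity = recall `TP/(TP+FN)` (the two names denote
#' the same quantity and are emitted as two equal fields for report-format
#' compatibility), specificity `TN/(TN+FP)`, F1 (harmonic mean of precision
#' and recall), the true/false positive rates, Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with chance agreement `p_e` from the marginal
#' products, and the proper/improper classified fractions. Ratios with a
#' zero denominator are reported as 0 and listed in the `undefined` field
#' with a warning, so degenerate cross-validation folds do not abort a
#' tuning run.
#'
#' @param cm A [confusion()] matrix with at least one counted sample.
#' @return An object of class `metrics_report`; all rates on the 0..1
#'   scale (the print method formats percentages).
#' @export
#' @examples
#' compute_metrics(confusion(rep(c("p", "n"), c(6, 4)),
#'                           rep(c("p", "n"), c(5, 5)), "p"))
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total < 1) stop("confusion matrix counts no samples")
  u <- new.env()
  u$flags <- character(0)
  accuracy <- (tp + tn) / total
  precision <- safe_ratio(tp, tp + fp, "precision", u)
  sensitivity <- safe_ratio(tp, tp + fn, "sensitivity", u)
  specificity <- safe_ratio(tn, tn + fp, "specificity", u)
  f1 <- if (precision + sensitivity == 0) {
    u$flags <- c(u$flags, "f1"); 0
  } else 2 * precision * sensitivity / (precision + sensitivity)
  p_o <- accuracy
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (p_e == 1) { u$flags <- c(u$flags, "kappa"); 0 } else
    (p_o - p_e) / (1 - p_e)
  fp_rate <- safe_ratio(fp, fp + tn, "fp_rate", u)
  if (length(u$flags)) {
    warning(sprintf("zero-denominator metric(s) reported as 0: %s",
                    paste(unique(u$flags), collapse = ", ")))
  }
  structure(
    list(accuracy = accuracy, precision = precision,
         sensitivity = sensitivity, recall = sensitivity,
         specificity = specificity, f1 = f1, kappa = kappa,
         tp_rate = sensitivity, fp_rate = fp_rate,
         proper_classified = accuracy, improper_classified = 1 - accuracy,
         counts = list(tp = tp, fp = fp, tn = tn, fn = fn, total = total),
         positive = cm$positive, undefined = unique(u$flags)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (positive class '%s', n = %d):\n", x$positive,
              x$counts$total))
  for (m in c("accuracy", "precision", "sensitivity", "recall",
              "specificity", "f1", "kappa", "tp_rate", "fp_rate")) {
    cat(sprintf("  %-12s %6.2f%%\n", m, 100 * x[[m]]))
  }
  if (!is.null(x$mae)) cat(sprintf("  %-12s %6.4f\n", "mae", x$mae))
  if (!is.null(x$rmse)) cat(sprintf("  %-12s %6.4f\n", "rmse", x$rmse))
  if (length(x$undefined)) {
    cat("  (zero-denominator, reported as 0:",
        paste(x$undefined, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Mean absolute and root-mean-square error of predicted probabilities
#'
#' Compares the positive-class probability against the 0/1 truth:
#' `MAE = mean |y - p|`, `RMSE = sqrt(mean (y - p)^2)`.
#'
#' @param y_true_binary Numeric 0/1 vector (1 = positive class).
#' @param y_score Positive-class probabilities in `[0, 1]`, same length.
#' @return A list with `mae` and `rmse`.
#' @export
#' @examples
#' mae_rmse(c(1, 0, 1), c(0.9, 0.2, 0.6))
mae_rmse <- function(y_true_binary, y_score) {
  if (length(y_true_binary) != length(y_score)) {
    stop("y_true_binary and y_score must have the same length")
  }
  if (any(y_score < 0 | y_score > 1)) stop("scores must lie in [0, 1]")
  if (!all(y_true_binary %in% c(0, 1))) stop("y_true_binary must be 0/1")
  d <- y_true_binary - y_score
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Side-by-side method comparison tables
#'
#' Formats one or several `metrics_report`s as an aligned text table (one
#' column per method, rates as percentages) and as a JSON document that
#' parses back to the exact values.
#'
#' @param reports A single `metrics_report` or a named list of them.
#' @param file Optional path; when given the JSON is written there.
#' @return Invisibly, a list with `text` (character vector of lines) and
#'   `json` (JSON string). The text table is also printed.
#' @export
report_tables <- function(reports, file = NULL) {
  if (inherits(reports, "metrics_report")) {
    reports <- list(model = reports)
  }
  stopifnot(length(reports) >= 1, all(vapply(reports, inherits,
                                             logical(1), "metrics_report")))
  rows <- c("proper_classified", "improper_classified", "accuracy",
            "precision", "sensitivity", "recall", "specificity", "f1",
            "kappa", "tp_rate", "fp_rate")
  fmt_pct <- function(v) sprintf("%.2f%%", 100 * v)
  header <- c("metric", names(reports))
  lines <- vapply(rows, function(m) {
    paste(formatC(c(m, vapply(reports, function(r) fmt_pct(r[[m]]),
                              character(1))),
                  width = max(nchar(header), 20), flag = "-"),
          collapse = " ")
  }, character(1))
  extra <- unlist(lapply(c("mae", "rmse", "train_time"), function(m) {
    if (all(vapply(reports, function(r) is.null(r[[m]]), logical(1)))) {
      return(character(0))
    }
    paste(formatC(c(m, vapply(reports, function(r)
      if (is.null(r[[m]])) "-" else sprintf("%.4f", r[[m]]), character(1))),
      width = max(nchar(header), 20), flag = "-"), collapse = " ")
  }))
  head_line <- paste(formatC(header, width = max(nchar(header), 20),
                             flag = "-"), collapse = " ")
  text <- c(head_line, lines, extra)
  json <- jsonlite::toJSON(
    lapply(reports, function(r) r[!vapply(r, is.null, logical(1))]),
    digits = NA, auto_unbox = TRUE, force = TRUE
  )
  if (!is.null(file)) writeLines(as.character(json), file)
  cat(text, sep = "\n")
  invisible(list(text = text, json = as.character(json)))
}
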