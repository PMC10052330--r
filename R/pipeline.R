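#' Pipeline configuration
#'
#' The end-to-end flow is fixed: normalize (with imputation) -> optional
#' discriminant feature extraction -> chi-squared weighting -> feature-
#' weighted forest, with optional swarm tuning of `(beta, k)` beforehand.
#' All randomness descends from the single `seed` via named sub-streams
#' ([derive_seed()]), so a config + seed pair pins the whole run.
#'
#' The discriminant stage is on by default (the canonical flow) but can be
#' disabled: with binary labels it projects to a single dimension, which is
#' the right call for deployment-sized models but removes any scope for the
#' weighted feature subsampling — ablation studies of the forest should
#' set `lda = FALSE`.
#'
#' @param seed Global integer seed.
#' @param new_min,new_max,impute,clip Preprocessing options, see
#'   [fit_preprocessor()].
#' @param lda Enable the discriminant projection stage (default `TRUE`).
#' @param lda_L,lda_ridge Options for [fit_lda()] (`NULL` = defaults).
#' @param bins,beta Chi-squared weighting options.
#' @param k,t,min_samples_leaf,max_depth,per_node_sampling Forest options.
#' @param tune Run [tune_asvrf()] before training (default `FALSE`).
#' @param tune_folds,tune_beta_range,tune_k_range,tune_pso Tuning options.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, new_min = 0, new_max = 1,
                            impute = "median", clip = TRUE,
                            lda = TRUE, lda_L = NULL, lda_ridge = NULL,
                            bins = 5L, beta = 0.5,
                            k = 50L, t = NULL, min_samples_leaf = 1L,
                            max_depth = Inf, per_node_sampling = FALSE,
                            tune = FALSE, tune_folds = 3L,
                            tune_beta_range = c(0.1, 1),
                            tune_k_range = c(5, 100), tune_pso = NULL) {
  structure(
    list(seed = as.integer(seed),
         preprocess = list(new_min = new_min, new_max = new_max,
                           impute = impute, clip = clip),
         lda = list(enabled = isTRUE(lda), L = lda_L, ridge = lda_ridge),
         weighting = list(bins = as.integer(bins), beta = beta),
         forest = list(k = as.integer(k), t = t,
                       min_samples_leaf = as.integer(min_samples_leaf),
                       max_depth = max_depth,
                       per_node_sampling = isTRUE(per_node_sampling)),
         tune = list(enabled = isTRUE(tune), folds = as.integer(tune_folds),
                     beta_range = tune_beta_range, k_range = tune_k_range,
                     pso = tune_pso)),
    class = "pipeline_config"
  )
}

serialize_pipeline_config <- function(cfg) {
  out <- unclass(cfg)
  if (is.infinite(out$forest$max_depth)) out$forest$max_depth <- NULL
  out$tune$pso <- NULL  # tuning state is not part of a trained bundle
  out
}

deserialize_pipeline_config <- function(l) {
  pipeline_config(
    seed = as.integer(l$seed),
    new_min = as.numeric(l$preprocess$new_min),
    new_max = as.numeric(l$preprocess$new_max),
    impute = as.character(l$preprocess$impute),
    clip = isTRUE(l$preprocess$clip),
    lda = isTRUE(l$lda$enabled),
    lda_L = if (is.null(l$lda$L)) NULL else as.integer(l$lda$L),
    lda_ridge = if (is.null(l$lda$ridge)) NULL else as.numeric(l$lda$ridge),
    bins = as.integer(l$weighting$bins),
    beta = as.numeric(l$weighting$beta),
    k = as.integer(l$forest$k),
    t = if (is.null(l$forest$t)) NULL else as.integer(l$forest$t),
    min_samples_leaf = as.integer(l$forest$min_samples_leaf),
    max_depth = if (is.null(l$forest$max_depth)) Inf
                else as.numeric(l$forest$max_depth),
    per_node_sampling = isTRUE(l$forest$per_node_sampling),
    tune = isTRUE(l$tune$enabled),
    tune_folds = as.integer(l$tune$folds),
    tune_beta_range = as.numeric(unlist(l$tune$beta_range)),
    tune_k_range = as.numeric(unlist(l$tune$k_range))
  )
}

pipeline_forest_config <- function(cfg) {
  forest_config(
    k = cfg$forest$k, beta = cfg$weighting$beta,
    t_override = cfg$forest$t,
    seed = derive_seed(cfg$seed, "forest"),
    tree = tree_config(min_samples_leaf = cfg$forest$min_samples_leaf,
                       max_depth = cfg$forest$max_depth),
    bins = cfg$weighting$bins,
    per_node_sampling = cfg$forest$per_node_sampling
  )
}

#' Train the full pipeline
#'
#' Fits the preprocessor on the training data, applies it, optionally fits
#' and applies the discriminant projection, optionally tunes `(beta, k)` by
#' swarm-searched cross-validation, and trains the feature-weighted forest.
#' Stage parameters and seeds are logged via `message()`.
#'
#' @param config A [pipeline_config()].
#' @param train An [asv_dataset] (use [read_csv_dataset()] for CSV input).
#' @return An object of class `asv_model`: `normalizer`, `lda` (or `NULL`),
#'   `forest`, `config`. Pass to [run_evaluate()], [predict_model()] or
#'   [save_model()].
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 10, readings_per_patient = 10,
#'                                   seed = 3))
#' bundle <- run_train(pipeline_config(seed = 3, k = 5, lda = FALSE),
#'                     co$dataset)
run_train <- function(config, train) {
  stopifnot(inherits(config, "pipeline_config"), inherits(train, "asv_dataset"))
  message(sprintf("[preprocess] fitting min-max normalizer (impute = %s) on %d rows",
                  config$preprocess$impute, n_obs(train)))
  pp <- fit_preprocessor(train, new_min = config$preprocess$new_min,
                         new_max = config$preprocess$new_max,
                         impute = config$preprocess$impute,
                         clip = config$preprocess$clip)
  work <- apply_preprocessor(pp, train)
  lda_model <- NULL
  if (config$lda$enabled) {
    lda_model <- fit_lda(work, L = config$lda$L, ridge = config$lda$ridge)
    message(sprintf("[lda] fitted discriminant subspace, L = %d", lda_model$L))
    work <- lda_project(lda_model, work)
  }
  fcfg <- pipeline_forest_config(config)
  if (config$tune$enabled) {
    message("[tune] swarm-searching (beta, k) by cross-validated error")
    fcfg <- tune_asvrf(work, beta_range = config$tune$beta_range,
                       k_range = config$tune$k_range,
                       folds = config$tune$folds,
                       pso = config$tune$pso, base = fcfg)
    message(sprintf("[tune] selected beta = %.3f, k = %d (CV error %.4f)",
                    fcfg$beta, fcfg$k, attr(fcfg, "cv_error")))
  }
  message(sprintf("[forest] training %d trees (beta = %.3f, seed = %d)",
                  fcfg$k, fcfg$beta, fcfg$seed))
  forest <- train_asv_rf(work, fcfg)
  message(sprintf("[forest] done; OOB accuracy %.4f", forest$oob_accuracy))
  structure(list(normalizer = pp, lda = lda_model, forest = forest,
                 config = config),
            class = "asv_model")
}

#' Predict with a trained bundle
#'
#' Applies the stored preprocessing (and projection, if fitted) and the
#' forest's probability-averaged vote.
#'
#' @param bundle An `asv_model`.
#' @param ds An [asv_dataset] with the training feature columns.
#' @return A list with `labels` (character) and `proba` (N x a matrix).
#' @export
predict_model <- function(bundle, ds) {
  stopifnot(inherits(bundle, "asv_model"), inherits(ds, "asv_dataset"))
  work <- apply_preprocessor(bundle$normalizer, ds)
  if (!is.null(bundle$lda)) work <- lda_project(bundle$lda, work)
  proba <- forest_predict_proba(bundle$forest, work)
  list(labels = bundle$forest$class_names[max.col(proba, ties.method = "first")],
       proba = proba)
}

#' Evaluate a trained bundle on labelled data
#'
#' Predicts, cross-tabulates against the truth and computes the full metric
#' suite; for binary problems the probability errors (MAE/RMSE of the
#' positive-class probability against the 0/1 truth) are attached.
#'
#' @param bundle An `asv_model` from [run_train()] or [load_model()].
#' @param test A labelled [asv_dataset] with the training feature columns.
#' @param positive_class Class treated as positive; defaults to the second
#'   training class (the "alarming" state of the synthetic cohorts).
#' @return A `metrics_report` (see [compute_metrics()]) with `mae`, `rmse`
#'   and the predictions in attribute `"predictions"`.
#' @export
run_evaluate <- function(bundle, test, positive_class = NULL) {
  stopifnot(inherits(bundle, "asv_model"), inherits(test, "asv_dataset"))
  classes <- bundle$forest$class_names
  positive_class <- positive_class %||%
    (if (length(classes) >= 2) classes[2] else classes[1])
  pred <- predict_model(bundle, test)
  truth <- label_names(test)
  report <- compute_metrics(confusion(truth, pred$labels, positive_class))
  if (positive_class %in% colnames(pred$proba)) {
    pe <- mae_rmse(as.numeric(truth == positive_class),
                   pred$proba[, positive_class])
    report$mae <- pe$mae
    report$rmse <- pe$rmse
  }
  attr(report, "predictions") <- pred
  report
}
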