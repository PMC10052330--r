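# Model bundles are stored as versioned, human-inspectable JSON: trees as
# nested objects, doubles at full precision (digits = NA) so a reloaded model
# predicts bit-identically.

BUNDLE_FORMAT <- "asvrf-model"
BUNDLE_VERSION <- 1L

mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m))
mat_from_list <- function(l) {
  matrix(as.numeric(unlist(l$data)), unlist(l$dim)[1], unlist(l$dim)[2])
}

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", prob = as.numeric(node$prob), n = node$n)
  } else {
    list(type = "split", feature = node$feature, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(l) {
  if (l$type == "leaf") {
    list(type = "leaf", prob = as.numeric(unlist(l$prob)),
         n = as.integer(l$n))
  } else {
    list(type = "split", feature = as.integer(l$feature),
         threshold = as.numeric(l$threshold),
         left = node_from_list(l$left), right = node_from_list(l$right))
  }
}

forest_to_list <- function(f) {
  list(
    trees = lapply(f$trees, node_to_list),
    feature_subsets = lapply(f$feature_subsets, as.integer),
    selected = as.integer(f$selected),
    t = f$t,
    weights = list(weights = as.numeric(f$weights$weights),
                   order = as.integer(f$weights$order),
                   edges = lapply(f$weights$edges, as.numeric),
                   bins = f$weights$bins),
    tree_seeds = as.integer(f$tree_seeds),
    config = forest_config_to_list(f$config),
    class_names = f$class_names,
    feature_names = f$feature_names,
    oob_accuracy = if (is.na(f$oob_accuracy)) NULL else f$oob_accuracy
  )
}

forest_from_list <- function(l) {
  w <- list(weights = as.numeric(unlist(l$weights$weights)),
            order = as.integer(unlist(l$weights$order)),
            edges = lapply(l$weights$edges,
                           function(e) as.numeric(unlist(e))),
            bins = as.integer(l$weights$bins))
  names(w$weights) <- as.character(unlist(l$feature_names))
  class(w) <- "feature_weights"
  structure(
    list(trees = lapply(l$trees, node_from_list),
         feature_subsets = lapply(l$feature_subsets,
                                  function(s) as.integer(unlist(s))),
         selected = as.integer(unlist(l$selected)),
         t = as.integer(l$t),
         weights = w,
         tree_seeds = as.integer(unlist(l$tree_seeds)),
         config = forest_config_from_list(l$config),
         class_names = as.character(unlist(l$class_names)),
         feature_names = as.character(unlist(l$feature_names)),
         oob_accuracy = if (is.null(l$oob_accuracy)) NA_real_
                        else as.numeric(l$oob_accuracy)),
    class = "asv_forest"
  )
}

tree_config_to_list <- function(tc) {
  list(min_samples_leaf = tc$min_samples_leaf,
       max_depth = if (is.finite(tc$max_depth)) tc$max_depth else NULL,
       min_gain_ratio = tc$min_gain_ratio)
}

tree_config_from_list <- function(l) {
  tree_config(min_samples_leaf = as.integer(l$min_samples_leaf),
              max_depth = if (is.null(l$max_depth)) Inf
                          else as.numeric(l$max_depth),
              min_gain_ratio = as.numeric(l$min_gain_ratio))
}

forest_config_to_list <- function(fc) {
  list(k = fc$k, beta = fc$beta, t_override = fc$t_override, seed = fc$seed,
       tree = tree_config_to_list(fc$tree), bins = fc$bins,
       per_node_sampling = fc$per_node_sampling)
}

forest_config_from_list <- function(l) {
  forest_config(k = as.integer(l$k), beta = as.numeric(l$beta),
                t_override = if (is.null(l$t_override)) NULL
                             else as.integer(l$t_override),
                seed = as.integer(l$seed),
                tree = tree_config_from_list(l$tree),
                bins = as.integer(l$bins),
                per_node_sampling = isTRUE(l$per_node_sampling))
}

preprocessor_to_list <- function(p) unclass(p)

preprocessor_from_list <- function(l) {
  structure(
    list(d_min = as.numeric(unlist(l$d_min)),
         d_max = as.numeric(unlist(l$d_max)),
         new_min = as.numeric(l$new_min), new_max = as.numeric(l$new_max),
         impute = as.character(l$impute),
         impute_values = as.numeric(unlist(l$impute_values)),
         clip = isTRUE(l$clip),
         feature_names = as.character(unlist(l$feature_names))),
    class = "asv_preprocessor"
  )
}

lda_to_list <- function(m) {
  list(W = mat_to_list(m$W), eigenvalues = as.numeric(m$eigenvalues),
       class_means = mat_to_list(m$class_means), mean = as.numeric(m$mean),
       L = m$L, ridge = m$ridge, feature_names = m$feature_names,
       class_names = m$class_names)
}

lda_from_list <- function(l) {
  structure(
    list(W = mat_from_list(l$W),
         eigenvalues = as.numeric(unlist(l$eigenvalues)),
         class_means = mat_from_list(l$class_means),
         mean = as.numeric(unlist(l$mean)),
         L = as.integer(l$L), ridge = as.numeric(l$ridge),
         feature_names = as.character(unlist(l$feature_names)),
         class_names = as.character(unlist(l$class_names))),
    class = "lda_model"
  )
}

#' Save a trained model bundle as versioned JSON
#'
#' The bundle (normalizer, optional discriminant model, forest, pipeline
#' configuration) round-trips losslessly: a loaded model produces
#' bit-identical predictions. An empty forest is rejected.
#'
#' @param bundle An `asv_model` from [run_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "asv_model"))
  if (is.null(bundle$forest) || length(bundle$forest$trees) < 1) {
    stop("refusing to save a bundle with an empty forest")
  }
  obj <- list(
    format = BUNDLE_FORMAT, version = BUNDLE_VERSION,
    normalizer = preprocessor_to_list(bundle$normalizer),
    lda = if (is.null(bundle$lda)) NULL else lda_to_list(bundle$lda),
    forest = forest_to_list(bundle$forest),
    config = serialize_pipeline_config(bundle$config)
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly,
  # which is what makes reloaded models predict bit-identically
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param path Path to the JSON bundle.
#' @return An `asv_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("corrupt model file '%s': %s",
                                     path, conditionMessage(e)))
  )
  if (!identical(obj$format, BUNDLE_FORMAT)) {
    stop("not an asvrf model bundle")
  }
  if (!identical(as.integer(obj$version), BUNDLE_VERSION)) {
    stop(sprintf("model bundle version %s is not supported (expected %d)",
                 obj$version, BUNDLE_VERSION))
  }
  structure(
    list(normalizer = preprocessor_from_list(obj$normalizer),
         lda = if (is.null(obj$lda)) NULL else lda_from_list(obj$lda),
         forest = forest_from_list(obj$forest),
         config = deserialize_pipeline_config(obj$config)),
    class = "asv_model"
  )
}
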