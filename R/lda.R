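#' Between- and within-class scatter matrices
#'
#' Computes the two n x n scatter matrices of Fisher discriminant analysis:
#' the between-class scatter `S_C = sum_k M_k (mu_k - mu)(mu_k - mu)^T`
#' (class sizes `M_k`, class means `mu_k`, global mean `mu`) and the
#' within-class scatter `S_V = sum_k sum_{x in X_k} (x - mu_k)(x - mu_k)^T`.
#' Both are symmetric positive semi-definite and their sum equals the total
#' scatter `sum_x (x - mu)(x - mu)^T`.
#'
#' @param ds An [asv_dataset] without missing values (run the preprocessor
#'   first) in which every declared class has at least one member.
#' @return A list with symmetric matrices `S_C` (between) and `S_V` (within),
#'   plus `class_means` (a x n), `mean`, and `class_sizes`.
#' @export
scatter_matrices <- function(ds) {
  stopifnot(inherits(ds, "asv_dataset"))
  X <- ds$features
  if (anyNA(X)) stop("missing values present; apply the preprocessor first")
  a <- n_classes(ds)
  sizes <- tabulate(ds$labels, a)
  if (any(sizes == 0)) {
    stop(sprintf("class '%s' has no members", ds$class_names[which(sizes == 0)[1]]))
  }
  n <- ncol(X)
  mu <- colMeans(X)
  M <- matrix(0, a, n)
  S_C <- matrix(0, n, n)
  S_V <- matrix(0, n, n)
  for (k in seq_len(a)) {
    Xk <- X[ds$labels == k, , drop = FALSE]
    mk <- colMeans(Xk)
    M[k, ] <- mk
    d <- mk - mu
    S_C <- S_C + sizes[k] * tcrossprod(d)
    S_V <- S_V + crossprod(sweep(Xk, 2, mk))
  }
  list(S_C = S_C, S_V = S_V, class_means = M, mean = mu, class_sizes = sizes)
}

#' Fit a linear discriminant subspace
#'
#' Solves the generalized eigenproblem `S_C w = psi (S_V + ridge I) w` and
#' keeps the eigenvectors of the L largest eigenvalues as the discriminant
#' basis W (columns unit-normalized; sign fixed so the largest-magnitude
#' component of each column is positive, which makes serialized models
#' reproducible). The Tikhonov ridge keeps the problem well-posed when the
#' within-class scatter is singular (few samples, collinear features); the
#' default is `1e-6 * trace(S_V) / n`.
#'
#' At most `a - 1` eigenvalues can be strictly positive, so the subspace
#' dimension is limited to `L <= min(n, a - 1)`.
#'
#' @param ds An [asv_dataset] without missing values.
#' @param L Subspace dimension, `1 <= L <= min(n, a - 1)`;
#'   default `min(n, a - 1)`.
#' @param ridge Non-negative Tikhonov regularizer added to `S_V`.
#' @return An object of class `lda_model` with elements `W` (n x L basis),
#'   `eigenvalues` (decreasing), `class_means`, `mean`, `L`, `ridge`,
#'   `feature_names`, `class_names`.
#' @export
#' @examples
#' ds <- asv_dataset(matrix(c(rnorm(30), rnorm(30, 3)), ncol = 2),
#'                   rep(c("a", "b"), each = 15))
#' m <- fit_lda(ds)
#' m$eigenvalues
fit_lda <- function(ds, L = NULL, ridge = NULL) {
  stopifnot(inherits(ds, "asv_dataset"))
  n <- n_features(ds)
  a <- n_classes(ds)
  L_max <- min(n, a - 1)
  L <- L %||% L_max
  if (L < 1 || L > L_max) {
    stop(sprintf("L must lie in [1, min(n, a - 1)] = [1, %d]", L_max))
  }
  sc <- scatter_matrices(ds)
  if (is.null(ridge)) {
    tr <- sum(diag(sc$S_V))
    ridge <- if (tr > 0) 1e-6 * tr / n else 1e-6
  }
  if (ridge < 0) stop("ridge must be non-negative")
  Sv <- sc$S_V + diag(ridge, n)
  M <- tryCatch(solve(Sv, sc$S_C), error = function(e) {
    stop(sprintf(paste0("within-class scatter is numerically singular even ",
                        "with ridge = %g; raise `ridge`"), ridge))
  })
  eig <- eigen(M)
  vals <- Re(eig$values)
  ord <- order(vals, decreasing = TRUE)[seq_len(L)]
  W <- Re(eig$vectors[, ord, drop = FALSE])
  for (j in seq_len(L)) {
    w <- W[, j]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    W[, j] <- w
  }
  structure(
    list(W = W, eigenvalues = vals[ord], class_means = sc$class_means,
         mean = sc$mean, L = as.integer(L), ridge = ridge,
         feature_names = ds$feature_names, class_names = ds$class_names),
    class = "lda_model"
  )
}

#' Project a dataset into a fitted discriminant subspace
#'
#' Returns the N x L projections `W^T x` per row; labels are carried through
#' unchanged. Projected features are named `LD1..LDL`.
#'
#' @param model An `lda_model` from [fit_lda()].
#' @param ds An [asv_dataset] whose feature count matches the model.
#' @return An [asv_dataset] with `L` features.
#' @export
lda_project <- function(model, ds) {
  stopifnot(inherits(model, "lda_model"), inherits(ds, "asv_dataset"))
  if (n_features(ds) != nrow(model$W)) {
    stop(sprintf("dataset has %d features but the model expects %d",
                 n_features(ds), nrow(model$W)))
  }
  if (anyNA(ds$features)) {
    stop("missing values present; apply the preprocessor first")
  }
  Z <- ds$features %*% model$W
  asv_dataset(Z, label_names(ds),
              feature_names = paste0("LD", seq_len(ncol(Z))),
              class_names = ds$class_names)
}
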