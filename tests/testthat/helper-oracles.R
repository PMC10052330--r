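# Independent oracles and small fixture builders, kept deliberately naive so
# they share no code path with the implementation they check.

# tiny labelled dataset from explicit vectors
toy_dataset <- function(..., labels) {
  asv_dataset(cbind(...), labels)
}

# brute-force scatter matrices: double loop over samples, straight from the
# outer-product definitions
oracle_scatter <- function(X, y) {
  classes <- unique(y)
  n <- ncol(X)
  mu <- colMeans(X)
  S_C <- matrix(0, n, n)
  S_V <- matrix(0, n, n)
  for (k in classes) {
    rows <- which(y == k)
    mk <- colMeans(X[rows, , drop = FALSE])
    d <- mk - mu
    S_C <- S_C + length(rows) * (d %*% t(d))
    for (i in rows) {
      e <- X[i, ] - mk
      S_V <- S_V + e %*% t(e)
    }
  }
  list(S_C = S_C, S_V = S_V)
}

# naive entropy in bits
oracle_entropy <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# exhaustive gain-ratio split search over every (feature, midpoint) pair;
# same tie conventions as the implementation contract: features ascending,
# thresholds ascending, keep the incumbent unless the challenger is better
# by more than 1e-12; splits need strictly positive information gain and
# min_samples_leaf rows on each side
oracle_best_split <- function(X, y, min_samples_leaf = 1, min_gain_ratio = 0) {
  n <- length(y)
  base <- oracle_entropy(y)
  best <- NULL
  best_gr <- -Inf
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- X[, f] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_samples_leaf || nr < min_samples_leaf) next
      gain <- base - (nl * oracle_entropy(y[left]) +
                        nr * oracle_entropy(y[!left])) / n
      if (gain <= 1e-12) next
      si <- -(nl / n * log2(nl / n) + nr / n * log2(nr / n))
      gr <- gain / si
      if (gr < min_gain_ratio) next
      if (gr > best_gr + 1e-12) {
        best_gr <- gr
        best <- list(feature = f, threshold = thr, gain_ratio = gr)
      }
    }
  }
  best
}

# standard contingency chi-squared statistic as an independent routine
oracle_chisq <- function(codes, labels) {
  unname(suppressWarnings(
    stats::chisq.test(table(codes, labels), correct = FALSE)$statistic
  ))
}

# small well-separated binary dataset for quick classifier checks
separable_dataset <- function(n_per_class = 25, n_features = 4, shift = 3,
                              seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- rbind(matrix(rnorm(n_per_class * n_features), n_per_class),
               matrix(rnorm(n_per_class * n_features, mean = shift),
                      n_per_class))
    asv_dataset(X, rep(c("a", "b"), each = n_per_class))
  })
}

# scaled-down benchmark cohort shared by the heavier tests: all generative
# parameters at the generator defaults, fewer readings per patient
bench_spec <- function(seed) {
  cohort_spec(readings_per_patient = 16L, seed = seed)
}
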