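#' Particle swarm configuration
#'
#' Canonical global-best PSO with a linearly decaying inertia weight:
#' the search starts near `w_max` (aggressive global exploration) and ends
#' at `w_min` (local refinement).
#'
#' @param dims Number of search dimensions D.
#' @param lower,upper Per-dimension bounds (recycled to length D),
#'   `lower < upper`.
#' @param np Swarm size (default 30, >= 2).
#' @param c1,c2 Cognitive and social acceleration constants (default 2).
#' @param w_max,w_min Initial and final inertia weights (defaults 0.9, 0.4).
#' @param iter_max Number of iterations (default 100).
#' @param clamp Velocity clamp as a fraction of each dimension's range
#'   (default 0.5).
#' @param seed Integer seed for the whole run.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(dims, lower, upper, np = 30L, c1 = 2, c2 = 2,
                       w_max = 0.9, w_min = 0.4, iter_max = 100L,
                       clamp = 0.5, seed = 1L) {
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (np < 2) stop("swarm size np must be >= 2")
  if (iter_max < 1) stop("iter_max must be >= 1")
  if (any(lower >= upper)) stop("every lower bound must be below its upper bound")
  if (w_max < w_min) stop("w_max must be >= w_min")
  if (c1 <= 0 || c2 <= 0) stop("acceleration constants must be positive")
  structure(
    list(dims = as.integer(dims), lower = lower, upper = upper,
         np = as.integer(np), c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
         iter_max = as.integer(iter_max), clamp = clamp,
         seed = as.integer(seed)),
    class = "pso_config"
  )
}

#' Linearly decaying inertia weight
#'
#' `w(iter) = w_max - (w_max - w_min) / iter_max * iter`, so
#' `w(0) = w_max` and `w(iter_max) = w_min` exactly.
#'
#' @param iter Current iteration, `0 <= iter <= iter_max`.
#' @param cfg A [pso_config()].
#' @return The inertia weight.
#' @export
#' @examples
#' cfg <- pso_config(1, -1, 1, w_max = 0.9, w_min = 0.4, iter_max = 100)
#' inertia_weight(50, cfg)  # 0.65
inertia_weight <- function(iter, cfg) {
  if (iter < 0 || iter > cfg$iter_max) {
    stop(sprintf("iter must lie in [0, %d]", cfg$iter_max))
  }
  cfg$w_max - (cfg$w_max - cfg$w_min) / cfg$iter_max * iter
}

eval_objective <- function(objective, X) {
  vals <- apply(X, 1, function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  })
  as.numeric(vals)
}

pso_init <- function(objective, cfg) {
  X <- matrix(stats::runif(cfg$np * cfg$dims), cfg$np, cfg$dims)
  X <- sweep(sweep(X, 2, cfg$upper - cfg$lower, `*`), 2, cfg$lower, `+`)
  vals <- eval_objective(objective, X)
  g <- which.min(vals)
  list(positions = X, velocities = matrix(0, cfg$np, cfg$dims),
       pbest = X, pbest_val = vals,
       gbest = X[g, ], gbest_val = vals[g], iter = 0L)
}

#' One particle swarm iteration
#'
#' Velocity update per particle and dimension:
#' `v <- w v + c1 rand() (pbest - x) + c2 rand() (gbest - x)`, with `w` from
#' [inertia_weight()] at the state's iteration counter; velocities are
#' clamped to `clamp * range`, positions move by `x <- x + v` and are
#' reflected back into the bounds (the velocity component flips sign at a
#' reflection). Personal and global bests update only on strict improvement,
#' so the global best value is non-increasing. A non-finite objective value
#' is recorded as `+Inf` and the particle keeps moving.
#'
#' Draws from the current RNG stream; [pso_optimize()] wraps the whole run
#' in the configured seed.
#'
#' @param state Swarm state as produced by [pso_optimize()] internals
#'   (positions, velocities, pbest, pbest_val, gbest, gbest_val, iter).
#' @param objective Function mapping a position vector to a scalar to
#'   minimize.
#' @param cfg A [pso_config()].
#' @return The updated state with `iter` advanced by one.
#' @export
pso_step <- function(state, objective, cfg) {
  w <- inertia_weight(state$iter, cfg)
  np <- cfg$np; D <- cfg$dims
  r1 <- matrix(stats::runif(np * D), np, D)
  r2 <- matrix(stats::runif(np * D), np, D)
  G <- matrix(state$gbest, np, D, byrow = TRUE)
  V <- w * state$velocities +
    cfg$c1 * r1 * (state$pbest - state$positions) +
    cfg$c2 * r2 * (G - state$positions)
  vmax <- matrix(cfg$clamp * (cfg$upper - cfg$lower), np, D, byrow = TRUE)
  V <- pmin(pmax(V, -vmax), vmax)
  X <- state$positions + V
  lo <- matrix(cfg$lower, np, D, byrow = TRUE)
  hi <- matrix(cfg$upper, np, D, byrow = TRUE)
  for (r in 1:10) {  # one reflection suffices under the clamp; loop for safety
    below <- X < lo; above <- X > hi
    if (!any(below | above)) break
    X[below] <- 2 * lo[below] - X[below]
    X[above] <- 2 * hi[above] - X[above]
    V[below | above] <- -V[below | above]
  }
  X <- pmin(pmax(X, lo), hi)
  vals <- eval_objective(objective, X)
  improved <- vals < state$pbest_val
  state$pbest[improved, ] <- X[improved, , drop = FALSE]
  state$pbest_val[improved] <- vals[improved]
  g <- which.min(state$pbest_val)
  if (state$pbest_val[g] < state$gbest_val) {
    state$gbest <- state$pbest[g, ]
    state$gbest_val <- state$pbest_val[g]
  }
  state$positions <- X
  state$velocities <- V
  state$iter <- state$iter + 1L
  state
}

#' Run a full particle swarm minimization
#'
#' Initializes positions uniformly in the bounds with zero velocities, then
#' performs `iter_max` steps. The entire run is reproducible from
#' `cfg$seed`.
#'
#' @param objective Function mapping a position vector to a scalar.
#' @param cfg A [pso_config()].
#' @return A list with `par` (best position), `value` (best objective
#'   value), `trace` (global best value after initialization and after each
#'   iteration, length `iter_max + 1`, non-increasing), and the final
#'   `state`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(sphere, pso_config(2, -5, 5, iter_max = 50, seed = 1))
#' res$value
pso_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "pso_config"))
  with_seed(cfg$seed, {
    state <- pso_init(objective, cfg)
    trace <- numeric(cfg$iter_max + 1)
    trace[1] <- state$gbest_val
    for (it in seq_len(cfg$iter_max)) {
      state <- pso_step(state, objective, cfg)
      stopifnot(state$gbest_val <= trace[it])
      trace[it + 1] <- state$gbest_val
    }
    list(par = state$gbest, value = state$gbest_val, trace = trace,
         state = state)
  })
}

#' Tune forest hyperparameters by swarm-searched cross-validation
#'
#' Minimizes the mean stratified K-fold cross-validated misclassification
#' rate of the feature-weighted forest over the two free hyperparameters of
#' the training algorithm, `beta` (feature-selection fraction) and `k`
#' (ensemble size). Particles move in a continuous 2-D box; at evaluation
#' the position is decoded by clipping `beta` into (0, 1] and rounding `k`
#' to an integer. Fold assignment is seeded once so the objective is a
#' deterministic function of position, and decoded configurations are
#' memoized to avoid re-training identical settings.
#'
#' @param train An [asv_dataset] without missing values.
#' @param beta_range,k_range Numeric length-2 search ranges.
#' @param folds Number of stratified CV folds (>= 2).
#' @param pso Optional [pso_config()]; defaults to a small swarm
#'   (`np = 6`, `iter_max = 8`) suitable for the expensive objective.
#' @param base A [forest_config()] supplying all non-tuned settings and the
#'   seed.
#' @return The best [forest_config()] found, with attributes `cv_error`
#'   (its cross-validated error) and `trace`.
#' @export
tune_asvrf <- function(train, beta_range = c(0.1, 1), k_range = c(5, 100),
                       folds = 3, pso = NULL, base = forest_config()) {
  stopifnot(inherits(train, "asv_dataset"))
  if (folds < 2) stop("folds must be >= 2")
  if (beta_range[1] <= 0 || beta_range[2] > 1 || diff(beta_range) < 0) {
    stop("beta_range must lie within (0, 1]")
  }
  if (k_range[1] < 1 || diff(k_range) < 0) stop("k_range must lie within [1, Inf)")
  fold_id <- make_stratified_folds(train$labels, folds,
                                   derive_seed(base$seed, "cv"))
  pso <- pso %||% pso_config(2, lower = c(beta_range[1], k_range[1]),
                             upper = c(beta_range[2], k_range[2]),
                             np = 6L, iter_max = 8L,
                             seed = derive_seed(base$seed, "pso"))
  memo <- new.env(parent = emptyenv())
  decode <- function(pos) {
    list(beta = min(max(pos[1], 1e-6), 1),
         k = max(1L, as.integer(round(pos[2]))))
  }
  objective <- function(pos) {
    d <- decode(pos)
    key <- sprintf("%.8f|%d", d$beta, d$k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    errs <- vapply(seq_len(folds), function(f) {
      tr <- ds_subset(train, which(fold_id != f))
      te <- ds_subset(train, which(fold_id == f))
      cfg <- base
      cfg$beta <- d$beta
      cfg$k <- d$k
      cfg$seed <- derive_seed(base$seed, "tune-forest")
      fit <- train_asv_rf(tr, cfg)
      mean(forest_predict(fit, te) != label_names(te))
    }, numeric(1))
    memo[[key]] <- mean(errs)
    memo[[key]]
  }
  res <- pso_optimize(objective, pso)
  d <- decode(res$par)
  out <- base
  out$beta <- d$beta
  out$k <- d$k
  attr(out, "cv_error") <- res$value
  attr(out, "trace") <- res$trace
  out
}

# stratified fold ids 1..folds, seeded
make_stratified_folds <- function(labels, folds, seed) {
  id <- integer(length(labels))
  with_seed(seed, {
    for (k in unique(labels)) {
      rows <- which(labels == k)
      if (length(rows) < folds) {
        stop("a class has fewer members than the number of folds")
      }
      id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })
  id
}
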