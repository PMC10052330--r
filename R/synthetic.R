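#' Parameters of a synthetic monitoring cohort
#'
#' Describes a two-class e-health-like cohort of repeated continuous
#' readings: `n_patients` subjects contribute `readings_per_patient` rows
#' each. A subset of features is informative — correlated Gaussians whose
#' class means differ by `class_separation` standard deviations per feature
#' — while the noise features are independent standard Gaussians identical
#' across classes. Each row carries a binary "normal"/"alarming" label drawn
#' with probability `class_balance` of "alarming", and cells go missing
#' completely at random at `missing_rate`. The defaults emulate a cohort of
#' 62 monitored patients with roughly 12.6 thousand readings and 5
#' informative channels, plus 15 noise features, 20% missingness and a
#' per-feature separation of 1.5 SD.
#'
#' @param n_patients Number of subjects (default 62).
#' @param readings_per_patient Rows per subject (default 203).
#' @param n_informative Number of informative features (default 5).
#' @param n_noise Number of pure-noise features (default 15).
#' @param class_separation Standardized mean shift per informative feature
#'   (default 1.5).
#' @param class_balance Probability of the "alarming" class, in (0, 1)
#'   (default 0.5).
#' @param missing_rate MCAR cell-missingness rate in [0, 1) (default 0.2).
#' @param feature_correlation Equicorrelation of the informative features,
#'   in [0, 1) (default 0.2).
#' @param patient_effect_sd SD of a per-patient random intercept added to
#'   the informative features (default 0, i.e. i.i.d. rows).
#' @param seed Integer seed; identical specs give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 62L, readings_per_patient = 203L,
                        n_informative = 5L, n_noise = 15L,
                        class_separation = 1.5, class_balance = 0.5,
                        missing_rate = 0.2, feature_correlation = 0.2,
                        patient_effect_sd = 0, seed = 1L) {
  if (n_patients < 1 || readings_per_patient < 1) {
    stop("n_patients and readings_per_patient must be >= 1")
  }
  if (n_informative < 1) stop("n_informative must be >= 1")
  if (n_noise < 0) stop("n_noise must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (class_balance <= 0 || class_balance >= 1) stop("class_balance must lie in (0, 1)")
  if (feature_correlation < 0 || feature_correlation >= 1) {
    stop("feature_correlation must lie in [0, 1)")
  }
  if (class_separation < 0) stop("class_separation must be >= 0")
  if (patient_effect_sd < 0) stop("patient_effect_sd must be >= 0")
  structure(
    list(n_patients = as.integer(n_patients),
         readings_per_patient = as.integer(readings_per_patient),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         class_separation = class_separation, class_balance = class_balance,
         missing_rate = missing_rate,
         feature_correlation = feature_correlation,
         patient_effect_sd = patient_effect_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a seeded synthetic cohort with planted ground truth
#'
#' Draws the cohort described by a [cohort_spec()]. Informative features
#' come first (`inf1..`), noise features after (`noise1..`); the returned
#' ground truth records the informative indices and the generating
#' parameters, so recovery tests can check whether the feature-weighting
#' stage finds the planted signal. Identical specs (including seed) give
#' identical datasets.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `dataset` (an [asv_dataset], classes
#'   `"normal"`/`"alarming"`), `truth` (informative indices, the generating parameters, the
#'   Mahalanobis separation `delta` and the Bayes error), and `patient`
#'   (integer subject id per row).
#' @export
#' @examples
#' gc <- generate_cohort(cohort_spec(n_patients = 4, readings_per_patient = 10,
#'                                   seed = 7))
#' gc$dataset
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$n_patients * spec$readings_per_patient
  f <- spec$n_informative
  q <- spec$n_noise
  patient <- rep(seq_len(spec$n_patients), each = spec$readings_per_patient)
  rho <- spec$feature_correlation
  Sigma <- matrix(rho, f, f); diag(Sigma) <- 1
  R <- chol(Sigma)
  ds <- with_seed(spec$seed, {
    y <- stats::rbinom(N, 1L, spec$class_balance)        # 1 = alarming
    u <- stats::rnorm(spec$n_patients, 0, spec$patient_effect_sd)
    Z <- matrix(stats::rnorm(N * f), N, f) %*% R
    Xi <- Z + spec$class_separation * y + u[patient]
    X <- if (q > 0) cbind(Xi, matrix(stats::rnorm(N * q), N, q)) else Xi
    if (spec$missing_rate > 0) {
      X[stats::runif(length(X)) < spec$missing_rate] <- NA_real_
    }
    asv_dataset(X, ifelse(y == 1, "alarming", "normal"),
                feature_names = c(paste0("inf", seq_len(f)),
                                  if (q > 0) paste0("noise", seq_len(q))),
                class_names = c("normal", "alarming"))
  })
  delta <- mahalanobis_separation(spec)
  list(dataset = ds,
       truth = list(informative = seq_len(f), spec = spec, delta = delta,
                    bayes_error = bayes_error(spec)),
       patient = patient)
}

mahalanobis_separation <- function(spec) {
  f <- spec$n_informative
  rho <- spec$feature_correlation
  Sigma <- matrix(rho + spec$patient_effect_sd^2, f, f)
  diag(Sigma) <- 1 + spec$patient_effect_sd^2
  delta_vec <- rep(spec$class_separation, f)
  sqrt(drop(crossprod(delta_vec, solve(Sigma, delta_vec))))
}

#' Bayes error of the synthetic generative model
#'
#' Closed-form minimum achievable misclassification rate for the cohort's
#' two-Gaussian model with shared covariance: with Mahalanobis distance
#' `Delta` between the class means and prior `pi1` on the alarming class,
#' the optimal rule thresholds the discriminant score at
#' `c = log((1 - pi1)/pi1)` and errs with probability
#' `pi1 Phi(c/Delta - Delta/2) + (1 - pi1) Phi(-c/Delta - Delta/2)`
#' (which reduces to `Phi(-Delta/2)` for balanced classes). The missingness
#' mechanism can only raise the achievable error, so this is a hard upper
#' bound on any classifier's accuracy under the model.
#'
#' @param spec A [cohort_spec()].
#' @return The Bayes error rate in [0, 0.5].
#' @export
#' @examples
#' # a Mahalanobis separation of 2 gives Phi(-1) ~ 0.1587 at balance
#' sp <- cohort_spec(n_informative = 1, class_separation = 2,
#'                   feature_correlation = 0)
#' bayes_error(sp)
bayes_error <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  delta <- mahalanobis_separation(spec)
  p1 <- spec$class_balance
  p0 <- 1 - p1
  if (delta == 0) return(min(p0, p1))
  cc <- log(p0 / p1)
  p1 * stats::pnorm(cc / delta - delta / 2) +
    p0 * stats::pnorm(-cc / delta - delta / 2)
}

#' Write a synthetic cohort to CSV plus ground-truth JSON
#'
#' @param cohort The list returned by [generate_cohort()].
#' @param csv_path Output CSV path (see [write_csv_dataset()]).
#' @param truth_path Optional path for the ground-truth JSON.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, csv_path, truth_path = NULL) {
  write_csv_dataset(cohort$dataset, csv_path)
  if (!is.null(truth_path)) {
    truth <- cohort$truth
    truth$spec <- unclass(truth$spec)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
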