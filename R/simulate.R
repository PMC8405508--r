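# Simulation of individual-level datasets and their aggregation into
# (mean vector, covariance matrix) summaries.

# Symmetric PSD square root used to scale standard-normal draws; chol()
# would reject the (perfectly legal) singular omegas that carry zero
# variances on some effects.
.omega_sqrt <- function(omega) {
  e <- eigen((omega + t(omega)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(1, max(abs(e$values))))
    stop("omega is not positive semi-definite (smallest eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Draw random-effect vectors for quasi-Monte-Carlo integration
#'
#' Generates `n_sim` random-effect vectors with covariance `omega`. The
#' "sobol" generator maps low-discrepancy points in (0,1)^v through the
#' inverse standard-normal CDF and scales them by a square root of omega; it
#' is deterministic given (v, n_sim). The "pseudo" generator uses seeded
#' normal draws.
#'
#' The returned object keeps the unscaled standard-normal points `Z` so the
#' same quasi-random sample can be re-scaled to candidate omegas during
#' estimation (common random numbers).
#'
#' @param omega Random-effect covariance matrix (or diagonal vector).
#' @param n_sim Number of vectors, >= 1.
#' @param generator "sobol" (default) or "pseudo".
#' @param seed Integer seed, used by the pseudo generator only.
#' @return Object of class `re_sample` with elements `B` (n_sim x v),
#'   `Z` (standard-normal points), `generator`, `n_sim`.
#' @export
sample_random_effects <- function(omega, n_sim, generator = c("sobol", "pseudo"),
                                  seed = 1L) {
  generator <- match.arg(generator)
  if (is.null(dim(omega))) omega <- diag(as.numeric(omega), nrow = length(omega))
  v <- nrow(omega)
  n_sim <- as.integer(n_sim)
  if (n_sim < 1) stop("n_sim must be >= 1")
  Z <- if (generator == "sobol") {
    stats::qnorm(sobol_points(n_sim, v))
  } else {
    set.seed(seed)
    matrix(stats::rnorm(n_sim * v), n_sim, v)
  }
  structure(list(B = scale_random_effects(Z, omega), Z = Z,
                 generator = generator, n_sim = n_sim),
            class = "re_sample")
}

#' Re-scale standard-normal quasi-random points to a covariance
#'
#' @param Z n x v matrix of standard-normal (quasi-)random points.
#' @param omega Target covariance matrix.
#' @return n x v matrix with rows distributed (quasi-)N(0, omega).
#' @export
scale_random_effects <- function(Z, omega) {
  if (is.null(dim(omega))) omega <- diag(as.numeric(omega), nrow = length(omega))
  Z %*% .omega_sqrt(omega)
}

#' Simulated individual-level dataset
#'
#' @param Y N x K matrix of observations (one subject per row, balanced).
#' @param design The shared [pk_design()].
#' @param subject_ids Optional identifiers (default 1..N).
#' @return Object of class `individual_dataset`.
#' @export
individual_dataset <- function(Y, design, subject_ids = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) != design$n_subjects)
    stop("row count of Y must equal design$n_subjects")
  if (ncol(Y) != length(design$times))
    stop("column count of Y must equal the number of sampling times")
  if (anyNA(Y)) stop("missing cells are not supported (balanced designs only)")
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(Y))
  structure(list(Y = Y, design = design, subject_ids = subject_ids),
            class = "individual_dataset")
}

#' @export
print.individual_dataset <- function(x, ...) {
  cat("Individual dataset:", nrow(x$Y), "subjects x", ncol(x$Y),
      "observations\n")
  invisible(x)
}

#' Simulate a balanced individual-level dataset
#'
#' Draws a random-effect vector per subject (seeded pseudo-random normal),
#' maps it to individual parameters, evaluates the structural model and adds
#' normal residual error with the model's residual variance. Concentrations
#' may go negative under additive error and are retained: the likelihood
#' assumes symmetric normal residuals.
#'
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param design A [pk_design()]; `design$n_subjects` subjects are simulated.
#' @param seed Integer seed.
#' @return An [individual_dataset()].
#' @export
simulate_individuals <- function(model, params, design, seed = 1L) {
  .check_params_model(params, model)
  N <- design$n_subjects
  K <- length(design$times)
  set.seed(seed)
  Z <- matrix(stats::rnorm(N * model$v), N, model$v)
  B <- scale_random_effects(Z, params$omega)
  theta <- param_map(params$beta, B, model$param_map_kind)
  F <- model$predict(theta, design)
  vres <- residual_variances(F, params, model$residual_kind)
  Y <- F + matrix(stats::rnorm(N * K), N, K) * sqrt(vres)
  individual_dataset(Y, design)
}

#' Observed aggregate data: mean vector and covariance matrix
#'
#' @param ybar Length-K mean vector.
#' @param V K x K covariance matrix of observations (population convention,
#'   denominator N).
#' @param n_subjects Number of subjects summarized.
#' @param times Sampling grid (provenance).
#' @return Object of class `aggregate_data`.
#' @export
aggregate_data <- function(ybar, V, n_subjects, times = NULL) {
  ybar <- as.numeric(ybar)
  V <- as.matrix(V)
  K <- length(ybar)
  if (!all(dim(V) == K)) stop("V must be K x K with K = length(ybar)")
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V)))) stop("V must be symmetric")
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("V is not positive semi-definite within tolerance")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects == 1 && max(abs(V)) > 0)
    stop("a single subject implies V = 0 exactly")
  structure(list(ybar = ybar, V = V, n_subjects = n_subjects, times = times),
            class = "aggregate_data")
}

#' @export
print.aggregate_data <- function(x, ...) {
  cat("Aggregate data:", length(x$ybar), "observation slots,",
      x$n_subjects, "subjects\n")
  cat("  mean:", paste(signif(x$ybar, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate a balanced individual dataset
#'
#' Computes the observed mean vector and the population-convention
#' covariance matrix of observations, `V_kl = mean((y_k - ybar_k)(y_l -
#' ybar_l))` with denominator N (not N - 1). The FO aggregate/individual
#' likelihood identity holds only with this convention.
#'
#' @param data An [individual_dataset()].
#' @return An [aggregate_data()].
#' @export
aggregate_observed <- function(data) {
  Y <- data$Y
  if (anyNA(Y)) stop("missing values are not supported")
  N <- nrow(Y)
  ybar <- colMeans(Y)
  Vc <- crossprod(sweep(Y, 2, ybar)) / N
  aggregate_data(ybar, Vc, N, times = data$design$times)
}
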