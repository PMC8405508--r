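# Model-expected aggregate moments (ytilde, Vtilde) under the FO, FOCE(I)
# and MC approximations.

#' Predicted aggregate moments container
#'
#' @param ytilde Length-K expected mean vector.
#' @param Vtilde K x K expected covariance matrix.
#' @param approximation One of "fo", "foce", "focei", "mc".
#' @param n_sim Quasi-Monte-Carlo sample size used (1 for FO).
#' @param interaction Whether the residual-error magnitude was evaluated at
#'   the simulated individual predictions ("interaction") rather than at the
#'   typical-subject prediction.
#' @return Object of class `predicted_moments`.
#' @export
predicted_moments <- function(ytilde, Vtilde, approximation, n_sim = 1L,
                              interaction = FALSE) {
  Vtilde <- (Vtilde + t(Vtilde)) / 2
  structure(list(ytilde = as.numeric(ytilde), Vtilde = Vtilde,
                 approximation = approximation, n_sim = as.integer(n_sim),
                 interaction = interaction),
            class = "predicted_moments")
}

#' @export
print.predicted_moments <- function(x, ...) {
  cat("Predicted aggregate moments (", toupper(x$approximation),
      if (x$approximation != "fo") paste0(", n_sim = ", x$n_sim), "):\n",
      sep = "")
  cat("  mean:", paste(signif(x$ytilde, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Jacobian of model predictions with respect to the random effects
#'
#' Central finite-difference Jacobian of `f(g(beta, b), design)` in `b`,
#' with per-element step `1e-5 * max(1, |b_j|)`. When `b` is a matrix of
#' random-effect vectors the Jacobians of all rows are evaluated in one
#' vectorized sweep per column.
#'
#' @param model A [structural_model()].
#' @param params A [pop_params()] (only `beta` is used).
#' @param b Random-effect vector, or n x v matrix.
#' @param design A [pk_design()].
#' @return K x v matrix for a vector `b`; an n x K x v array for a matrix.
#' @export
jacobian_re <- function(model, params, b, design) {
  single <- !is.matrix(b)
  B <- if (single) matrix(b, nrow = 1) else b
  n <- nrow(B); v <- ncol(B); K <- length(design$times)
  J <- array(0, dim = c(n, K, v))
  for (j in seq_len(v)) {
    h <- 1e-5 * pmax(1, abs(B[, j]))
    Bp <- B; Bp[, j] <- B[, j] + h
    Bm <- B; Bm[, j] <- B[, j] - h
    Fp <- model$predict(param_map(params$beta, Bp, model$param_map_kind), design)
    Fm <- model$predict(param_map(params$beta, Bm, model$param_map_kind), design)
    if (!all(is.finite(Fp)) || !all(is.finite(Fm)))
      stop("non-finite predictions at perturbed random effects")
    J[, , j] <- (Fp - Fm) / (2 * h)
  }
  if (single) matrix(J[1, , ], K, v) else J
}

# Average of J_i Omega J_i' across the sampled random-effect vectors.
.mean_JOJ <- function(Jarr, omega) {
  n <- dim(Jarr)[1]; K <- dim(Jarr)[2]
  L <- .omega_sqrt(omega)
  S <- matrix(0, K, K)
  for (i in seq_len(n)) {
    M <- matrix(Jarr[i, , ], K) %*% L
    S <- S + tcrossprod(M)
  }
  S / n
}

#' Model-expected aggregate moments
#'
#' Computes the expected mean vector and covariance matrix of observations
#' under the chosen approximation:
#' \describe{
#'   \item{fo}{Linearization at b = 0: `ytilde = f(g(beta, 0))`,
#'     `Vtilde = J Omega J' + diag(residual variances at the typical
#'     prediction)`.}
#'   \item{foce / focei}{Quasi-Monte-Carlo average of the conditional
#'     linearization over sampled random-effect vectors: the mean collects
#'     `f(theta_i) - J_i b_i`, the covariance averages `J_i Omega J_i'` plus
#'     the diagonal residual term -- evaluated at the typical prediction for
#'     "foce" and at the simulated individual predictions for "focei"
#'     (interaction).}
#'   \item{mc}{Moments of the residual-free simulated predictions
#'     (population-covariance denominator `n_sim`) plus the average diagonal
#'     residual term at the simulated predictions.}
#' }
#' Off-diagonals of the residual contribution are zero throughout: residuals
#' are independent across observations.
#'
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param design A [pk_design()].
#' @param approximation One of "fo", "foce", "focei", "mc".
#' @param sample Optional [sample_random_effects()] result; its
#'   standard-normal points are re-scaled to `params$omega`. Drawn with the
#'   Sobol generator when omitted.
#' @param n_sim Sample size when `sample` is omitted; defaults to
#'   `max(300, design$n_subjects)`.
#' @return A [predicted_moments()].
#' @export
expected_moments <- function(model, params, design,
                             approximation = c("fo", "foce", "focei", "mc"),
                             sample = NULL, n_sim = NULL) {
  approximation <- match.arg(approximation)
  .check_params_model(params, model)
  K <- length(design$times)
  f0 <- predict_model(model, param_map(params$beta, rep(0, model$v),
                                       model$param_map_kind), design)
  if (approximation == "fo") {
    J <- jacobian_re(model, params, rep(0, model$v), design)
    Vt <- J %*% params$omega %*% t(J) +
      diag(residual_variances(f0, params, model$residual_kind), K)
    return(predicted_moments(f0, Vt, "fo", 1L))
  }
  if (is.null(sample)) {
    if (is.null(n_sim)) n_sim <- max(300L, design$n_subjects)
    sample <- sample_random_effects(params$omega, n_sim, "sobol")
  }
  B <- scale_random_effects(sample$Z, params$omega)
  n <- nrow(B)
  theta <- param_map(params$beta, B, model$param_map_kind)
  F <- model$predict(theta, design)
  if (approximation == "mc") {
    ytilde <- colMeans(F)
    Vt <- crossprod(sweep(F, 2, ytilde)) / n +
      diag(colMeans(residual_variances(F, params, model$residual_kind)), K)
    return(predicted_moments(ytilde, Vt, "mc", n))
  }
  # foce / focei: conditional linearization averaged over the sample
  Jarr <- jacobian_re(model, params, B, design)
  corr <- F
  for (j in seq_len(model$v)) corr <- corr - Jarr[, , j] * B[, j]
  ytilde <- colMeans(corr)
  interaction <- approximation == "focei"
  rdiag <- if (interaction) {
    colMeans(residual_variances(F, params, model$residual_kind))
  } else {
    residual_variances(f0, params, model$residual_kind)
  }
  Vt <- .mean_JOJ(Jarr, params$omega) + diag(rdiag, K)
  predicted_moments(ytilde, Vt, approximation, n, interaction)
}
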