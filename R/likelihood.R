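# Individual-data FO/FOCE(I) and aggregate-data log-likelihoods.
#
# Convention: no 2*pi constants anywhere, matching the NONMEM-style
# objective function value OFV = -2 * loglik. This differs from the textbook
# multivariate-normal density by the constant K*log(2*pi) per subject.

# Large-penalty contract for a non-positive-definite predicted covariance:
# keeps the optimizer's surface finite and repulsive.
.PENALTY <- -1e10

# -1/2 (r' V^-1 r + log|V|) via Cholesky; penalty on failure.
.mvn_ll <- function(r, V) {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
    return(.PENALTY - abs(min(ev)))
  }
  z <- backsolve(U, r, transpose = TRUE)
  -0.5 * (sum(z^2) + 2 * sum(log(diag(U))))
}

#' Maximum a posteriori random-effect estimate for one subject
#'
#' Minimizes the conditional objective
#' `0.5 * (sum((y - f)^2 / v) + sum(log v)) + 0.5 * b' Omega^-1 b`
#' over the random-effect vector, where `v` is the residual variance at the
#' candidate prediction. Quasi-Newton (BFGS) from `b_init` (default 0).
#' Random effects whose omega variance is zero are held at zero.
#'
#' @param y_i Observation vector for the subject.
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param design A [pk_design()].
#' @param b_init Starting value (warm start across outer iterations).
#' @return List with `b` (the MAP vector), `value`, `converged`.
#' @export
map_random_effects <- function(y_i, model, params, design, b_init = NULL) {
  v <- model$v
  active <- diag(params$omega) > 0
  if (!any(active)) return(list(b = rep(0, v), value = NA_real_, converged = TRUE))
  Oa <- params$omega[active, active, drop = FALSE]
  Oinv <- solve(Oa)
  obj <- function(ba) {
    b <- rep(0, v); b[active] <- ba
    f <- predict_model(model, param_map(params$beta, b, model$param_map_kind),
                       design)
    vk <- residual_variances(f, params, model$residual_kind)
    if (any(vk <= 0) || !all(is.finite(f))) return(1e10)
    0.5 * (sum((y_i - f)^2 / vk) + sum(log(vk))) +
      0.5 * drop(ba %*% Oinv %*% ba)
  }
  start <- if (is.null(b_init)) rep(0, sum(active)) else b_init[active]
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  b <- rep(0, v); b[active] <- fit$par
  list(b = b, value = fit$value, converged = fit$convergence == 0)
}

#' Individual-data log-likelihood (FO, FOCE, FOCEI)
#'
#' Linearized multivariate-normal log-likelihood of a balanced individual
#' dataset. Per subject the residual is
#' `y_i - (f(theta_i) - J_i b_i)` with the Jacobian taken at the
#' linearization point (`b_i = 0` for FO, the MAP estimate for FOCE/FOCEI),
#' and the covariance is `J_i Omega J_i' + diag(residual variances)` --
#' evaluated at the typical prediction for FO/FOCE and at the individual
#' prediction for FOCEI.
#'
#' @param data An [individual_dataset()].
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param method "fo", "foce" or "focei".
#' @param warm_start Optional N x v matrix of starting values for the inner
#'   MAP problems.
#' @return List with `loglik` (total), and `workspaces`: a data frame of
#'   per-subject contributions and MAP estimates.
#' @export
loglik_individual <- function(data, model, params,
                              method = c("fo", "foce", "focei"),
                              warm_start = NULL) {
  method <- match.arg(method)
  .check_params_model(params, model)
  Y <- data$Y; design <- data$design
  N <- nrow(Y); K <- ncol(Y); v <- model$v
  f0 <- predict_model(model, param_map(params$beta, rep(0, v),
                                       model$param_map_kind), design)
  r0 <- residual_variances(f0, params, model$residual_kind)
  ll <- numeric(N)
  Bmap <- matrix(0, N, v)
  if (method == "fo") {
    J <- jacobian_re(model, params, rep(0, v), design)
    V <- J %*% params$omega %*% t(J) + diag(r0, K)
    for (i in seq_len(N)) ll[i] <- .mvn_ll(Y[i, ] - f0, V)
  } else {
    for (i in seq_len(N)) {
      bi <- map_random_effects(Y[i, ], model, params, design,
                               b_init = if (is.null(warm_start)) NULL else warm_start[i, ])
      Bmap[i, ] <- bi$b
      thi <- param_map(params$beta, bi$b, model$param_map_kind)
      fi <- predict_model(model, thi, design)
      Ji <- jacobian_re(model, params, bi$b, design)
      ri <- Y[i, ] - (fi - drop(Ji %*% bi$b))
      rd <- if (method == "focei") residual_variances(fi, params, model$residual_kind) else r0
      Vi <- Ji %*% params$omega %*% t(Ji) + diag(rd, K)
      ll[i] <- .mvn_ll(ri, Vi)
    }
  }
  list(loglik = sum(ll),
       workspaces = data.frame(id = data$subject_ids, loglik = ll,
                               b = I(Bmap)))
}

#' Aggregate-data log-likelihood
#'
#' The log-likelihood of observed aggregate data (mean vector `ybar`,
#' covariance `V`, `N` subjects) under predicted moments `(ytilde, Vtilde)`:
#' `-(N/2) * (tr(V Vtilde^-1) + (ybar - ytilde)' Vtilde^-1 (ybar - ytilde)
#' + log|Vtilde|)`, computed via Cholesky. With `N = 1` and `V = 0` this
#' equals the individual-data expression for that subject.
#'
#' @param agg An [aggregate_data()].
#' @param moments A [predicted_moments()].
#' @return Log-likelihood scalar (penalized finite value if `Vtilde` is not
#'   positive definite).
#' @export
loglik_aggregate <- function(agg, moments) {
  K <- length(agg$ybar)
  if (length(moments$ytilde) != K) stop("dimension mismatch")
  Vt <- moments$Vtilde
  U <- tryCatch(chol(Vt), error = function(e) NULL)
  if (is.null(U)) {
    ev <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE, only.values = TRUE)$values
    return(.PENALTY - abs(min(ev)))
  }
  Vinv <- chol2inv(U)
  r <- agg$ybar - moments$ytilde
  -agg$n_subjects / 2 * (sum(Vinv * agg$V) + drop(r %*% Vinv %*% r) +
                         2 * sum(log(diag(U))))
}

#' Objective function value
#'
#' `OFV = -2 * loglik`, the NONMEM reporting convention.
#'
#' @param loglik Log-likelihood scalar.
#' @return The objective function value.
#' @export
ofv <- function(loglik) -2 * loglik

#' Leave-one-out Monte-Carlo standard error of the aggregate log-likelihood
#'
#' Diagnostic for the quasi-Monte-Carlo sample size: each sampled
#' random-effect vector is left out in turn, the aggregate moments and
#' log-likelihood are recomputed from the remaining `n_sim - 1` vectors, and
#' the standard deviation of the leave-one-out log-likelihoods is divided by
#' the number of subjects in the dataset ("approximation standard error per
#' one subject"). No jackknife inflation factor is applied.
#'
#' @param agg An [aggregate_data()].
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param design The [pk_design()] the aggregate data were observed under
#'   (needed for dose information).
#' @param sample A [sample_random_effects()] result (n_sim >= 2); drawn with
#'   the Sobol generator when omitted.
#' @param approximation "mc" (default) or "foce"/"focei".
#' @param n_sim Sample size when `sample` is omitted (default 300).
#' @return List with `se_per_subject`, `loglik_full`, `loo_logliks`.
#' @export
loo_mc_se <- function(agg, model, params, design, sample = NULL,
                      approximation = c("mc", "foce", "focei"), n_sim = 300L) {
  approximation <- match.arg(approximation)
  if (is.null(sample)) sample <- sample_random_effects(params$omega, n_sim, "sobol")
  n <- sample$n_sim
  if (n < 2) stop("n_sim must be >= 2")
  B <- scale_random_effects(sample$Z, params$omega)
  theta <- param_map(params$beta, B, model$param_map_kind)
  F <- model$predict(theta, design)
  K <- ncol(F)
  Rv <- residual_variances(F, params, model$residual_kind)
  if (approximation == "mc") {
    M1 <- colSums(F); C2 <- crossprod(F); Rs <- colSums(Rv)
    ll <- function(rows_mean, rows_cross, rows_r, m) {
      mu <- rows_mean / m
      Vt <- rows_cross / m - tcrossprod(mu) + diag(rows_r / m, K)
      loglik_aggregate(agg, predicted_moments(mu, Vt, "mc", m))
    }
    full <- ll(M1, C2, Rs, n)
    loo <- vapply(seq_len(n), function(j)
      ll(M1 - F[j, ], C2 - tcrossprod(F[j, ]), Rs - Rv[j, ], n - 1L),
      numeric(1))
  } else {
    Jarr <- jacobian_re(model, params, B, design)
    corr <- F
    for (j in seq_len(model$v)) corr <- corr - Jarr[, , j] * B[, j]
    L <- .omega_sqrt(params$omega)
    Mlist <- lapply(seq_len(n), function(i)
      tcrossprod(matrix(Jarr[i, , ], K) %*% L))
    f0 <- predict_model(model, param_map(params$beta, rep(0, model$v),
                                         model$param_map_kind), design)
    rd0 <- residual_variances(f0, params, model$residual_kind)
    interaction <- approximation == "focei"
    Csum <- colSums(corr); Msum <- Reduce(`+`, Mlist); Rs <- colSums(Rv)
    ll <- function(cs, ms, rs, m) {
      rd <- if (interaction) rs / m else rd0
      Vt <- ms / m + diag(rd, K)
      loglik_aggregate(agg, predicted_moments(cs / m, Vt, approximation, m))
    }
    full <- ll(Csum, Msum, Rs, n)
    loo <- vapply(seq_len(n), function(j)
      ll(Csum - corr[j, ], Msum - Mlist[[j]], Rs - Rv[j, ], n - 1L),
      numeric(1))
  }
  list(se_per_subject = stats::sd(loo) / agg$n_subjects,
       loglik_full = full, loo_logliks = loo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
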