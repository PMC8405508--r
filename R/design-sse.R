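# Expected Fisher information via the numerical Hessian of the aggregate
# log-likelihood at expected aggregate data, the one-step "aggregate-data
# OD" replacement for stochastic simulation-and-estimation (SSE), and the
# SSE replication machinery itself.

#' Numerical Hessian by central differences with Richardson refinement
#'
#' Per-parameter relative step `rel_step * max(1, |x_j|)`; one Richardson
#' extrapolation step (the h and h/2 estimates combined as `(4 H_{h/2} -
#' H_h) / 3`) removes the leading O(h^2) error. Steps are taken on the scale
#' of `x` as given.
#'
#' @param fn Scalar function of a numeric vector.
#' @param x Evaluation point.
#' @param rel_step Relative step size (default 1e-4).
#' @param richardson Apply the refinement (default TRUE).
#' @return Symmetric p x p Hessian matrix.
#' @export
num_hessian <- function(fn, x, rel_step = 1e-4, richardson = TRUE) {
  hess_h <- function(h) {
    p <- length(x)
    H <- matrix(0, p, p)
    f0 <- fn(x)
    fp <- fm <- numeric(p)
    for (j in seq_len(p)) {
      ej <- numeric(p); ej[j] <- h[j]
      fp[j] <- fn(x + ej); fm[j] <- fn(x - ej)
      H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
    }
    if (p > 1) for (j in 1:(p - 1)) for (k in (j + 1):p) {
      ej <- numeric(p); ej[j] <- h[j]
      ek <- numeric(p); ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (fn(x + ej + ek) - fn(x + ej - ek) -
         fn(x - ej + ek) + fn(x - ej - ek)) / (4 * h[j] * h[k])
    }
    H
  }
  h <- rel_step * pmax(1, abs(x))
  H1 <- hess_h(h)
  if (!richardson) return((H1 + t(H1)) / 2)
  H2 <- hess_h(h / 2)
  H <- (4 * H2 - H1) / 3
  (H + t(H)) / 2
}

# Expected aggregate data simulated from a generating model under a chosen
# approximation of the moments.
.expected_aggregate <- function(model, params, design, approximation, n_sim,
                                sample = NULL) {
  mom <- expected_moments(model, params, design, approximation,
                          sample = sample, n_sim = n_sim)
  aggregate_data(mom$ytilde, mom$Vtilde, design$n_subjects,
                 times = design$times)
}

#' Expected Fisher information matrix from the aggregate log-likelihood
#'
#' Simulates the expected aggregate data from the generating model under the
#' chosen approximation, then takes the negative numerical Hessian of the
#' aggregate-data log-likelihood with respect to the analytic model's
#' parameters, on the natural (reported) scale. With `gen == ana` this is
#' classical optimal design; with different models it is optimal design
#' under model misspecification.
#'
#' @param gen_model,gen_params Data-generating [structural_model()] and
#'   [pop_params()].
#' @param design A [pk_design()] (its `n_subjects` scales the information).
#' @param ana_model,ana_params Data-analytic model and the parameter point
#'   the Hessian is taken at; default to the generating pair.
#' @param approximation Moments approximation for both the expected data and
#'   the likelihood: "fo", "foce", "focei" or "mc".
#' @param n_sim Quasi-Monte-Carlo sample size for non-FO approximations.
#' @param estimate Estimation mask for the analytic parameters, see
#'   [param_transform()].
#' @return Object of class `fim_result` with `fim`, `rse_percent`,
#'   `par_names`, `approximation`, `design`, `params`.
#' @export
expected_fim <- function(gen_model, gen_params, design,
                         ana_model = gen_model, ana_params = gen_params,
                         approximation = c("fo", "foce", "focei", "mc"),
                         n_sim = 300L, estimate = NULL) {
  approximation <- match.arg(approximation)
  agg <- .expected_aggregate(gen_model, gen_params, design, approximation,
                             n_sim)
  sample <- if (approximation == "fo") NULL else
    sample_random_effects(diag(ana_model$v), n_sim, "sobol")
  tr <- param_transform(ana_params, ana_model, estimate)
  x0 <- .free_param_values(ana_params, tr)
  fn <- function(x) {
    p <- tryCatch(.params_from_free(x, ana_params, tr),
                  error = function(e) NULL)
    if (is.null(p)) return(.PENALTY)
    val <- tryCatch(
      loglik_aggregate(agg, expected_moments(ana_model, p, design,
                                             approximation, sample = sample)),
      error = function(e) NA_real_)
    if (!is.finite(val)) return(.PENALTY)
    val
  }
  fim <- -num_hessian(fn, x0)
  cov <- tryCatch(solve(fim), error = function(e) NULL)
  rse <- if (is.null(cov) || any(diag(cov) <= 0)) rep(NA_real_, length(x0))
         else 100 * sqrt(diag(cov)) / abs(x0)
  structure(list(fim = fim, rse_percent = rse, par_names = tr$names,
                 approximation = approximation, design = design,
                 params = ana_params, n_sim = n_sim),
            class = "fim_result")
}

#' @export
print.fim_result <- function(x, ...) {
  cat("Expected FIM (", toupper(x$approximation), "), ",
      x$design$n_subjects, " subjects\n", sep = "")
  print(data.frame(parameter = x$par_names, rse_percent = x$rse_percent),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Linearized FO population Fisher information (independent oracle)
#'
#' The standard first-order population-FIM expression assembled from
#' finite-difference gradients of the FO moments with respect to the
#' parameters: `I_jk = N * (dy_j' V^-1 dy_k + 0.5 * tr(V^-1 dV_j V^-1
#' dV_k))`. Serves as an independent cross-check of [expected_fim()] under
#' the FO approximation; the two agree analytically.
#'
#' @param model A [structural_model()].
#' @param params A [pop_params()].
#' @param design A [pk_design()].
#' @param estimate Estimation mask, see [param_transform()].
#' @param rel_step Relative step for the moment gradients (default 1e-4; a
#'   Richardson refinement of the central differences is applied). Much
#'   smaller steps amplify the rounding noise of the finite-difference
#'   random-effect Jacobian inside the moments.
#' @return A `fim_result`.
#' @export
fo_fim_linearized <- function(model, params, design, estimate = NULL,
                              rel_step = 1e-4) {
  tr <- param_transform(params, model, estimate)
  x0 <- .free_param_values(params, tr)
  p <- length(x0)
  mom0 <- expected_moments(model, params, design, "fo")
  K <- length(mom0$ytilde)
  dy <- matrix(0, K, p)
  dV <- array(0, dim = c(K, K, p))
  cdiff <- function(j, h) {
    xp <- x0; xp[j] <- x0[j] + h
    xm <- x0; xm[j] <- x0[j] - h
    mp <- expected_moments(model, .params_from_free(xp, params, tr), design, "fo")
    mm <- expected_moments(model, .params_from_free(xm, params, tr), design, "fo")
    list(dy = (mp$ytilde - mm$ytilde) / (2 * h),
         dV = (mp$Vtilde - mm$Vtilde) / (2 * h))
  }
  for (j in seq_len(p)) {
    h <- rel_step * max(1, abs(x0[j]))
    g1 <- cdiff(j, h); g2 <- cdiff(j, h / 2)
    dy[, j] <- (4 * g2$dy - g1$dy) / 3
    dV[, , j] <- (4 * g2$dV - g1$dV) / 3
  }
  Vinv <- chol2inv(chol(mom0$Vtilde))
  fim <- matrix(0, p, p)
  W <- lapply(seq_len(p), function(j) Vinv %*% dV[, , j])
  for (j in seq_len(p)) for (k in j:p) {
    fim[j, k] <- fim[k, j] <-
      drop(dy[, j] %*% Vinv %*% dy[, k]) + 0.5 * sum(t(W[[j]]) * W[[k]])
  }
  fim <- design$n_subjects * fim
  cov <- tryCatch(solve(fim), error = function(e) NULL)
  rse <- if (is.null(cov) || any(diag(cov) <= 0)) rep(NA_real_, p)
         else 100 * sqrt(diag(cov)) / abs(x0)
  structure(list(fim = fim, rse_percent = rse, par_names = tr$names,
                 approximation = "fo", design = design, params = params,
                 n_sim = 1L),
            class = "fim_result")
}

#' One-step aggregate-data optimal design ("aggregate-data OD")
#'
#' The deterministic replacement for stochastic simulation-and-estimation:
#' simulate the expected aggregate data once from the data-generating model,
#' fit the data-analytic model to it by the requested aggregate-data method,
#' and attach Hessian-based expected standard errors. Data-generating and
#' data-analytic models may differ.
#'
#' @param gen_model,gen_params Data-generating model and parameters.
#' @param ana_model Data-analytic model.
#' @param init Initial [pop_params()] for the analytic model.
#' @param design A [pk_design()].
#' @param method Aggregate fitting method ("fo_aggregate", "foce_aggregate",
#'   "focei_aggregate" or "mc_aggregate").
#' @param gen_approximation Approximation used to simulate the expected
#'   aggregate data (default "mc").
#' @param n_sim Quasi-Monte-Carlo sample size (default 300).
#' @param estimate Estimation mask for the analytic model.
#' @param control Optimizer control, see [fit_model()].
#' @param compute_se Attach expected standard errors (default TRUE).
#' @return A `fit_result` with expected SEs.
#' @export
aggregate_od <- function(gen_model, gen_params, ana_model, init, design,
                         method = "mc_aggregate",
                         gen_approximation = c("mc", "fo", "foce", "focei"),
                         n_sim = 300L, estimate = NULL, control = list(),
                         compute_se = TRUE) {
  gen_approximation <- match.arg(gen_approximation)
  agg <- .expected_aggregate(gen_model, gen_params, design,
                             gen_approximation, n_sim)
  fit_model(agg, ana_model, init, method, design = design, n_sim = n_sim,
            estimate = estimate, control = control, compute_se = compute_se)
}

#' Stochastic simulation and estimation
#'
#' Simulates `n_replicates` individual-level datasets from the generating
#' model and fits the analytic model to each by the requested methods.
#' Aggregate methods ("*_aggregate") summarize each simulated dataset into
#' mean/covariance form before fitting; individual methods use the raw data.
#' Replicate seeds are derived from the master seed by a counter; failed
#' replicates are recorded and excluded from summaries.
#'
#' @param gen_model,gen_params Data-generating model and parameters.
#' @param ana_model Data-analytic model.
#' @param init Initial [pop_params()] for the analytic model.
#' @param design A [pk_design()] (defines N per replicate).
#' @param n_replicates Number of replicates, >= 2.
#' @param methods Character vector of [fit_model()] methods.
#' @param seed Master seed.
#' @param n_sim Quasi-Monte-Carlo sample size for aggregate FOCE/MC fits.
#' @param estimate Estimation mask for the analytic model.
#' @param control Optimizer control, see [fit_model()].
#' @return Object of class `sse_result` with `estimates` (long data frame:
#'   replicate, method, parameter, value, converged) and `summary` (per
#'   method and parameter: mean, sd over converged replicates, n_converged).
#' @export
run_sse <- function(gen_model, gen_params, ana_model, init, design,
                    n_replicates, methods = "fo_aggregate", seed = 1L,
                    n_sim = NULL, estimate = NULL, control = list()) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- (seed + 104729L * r) %% .Machine$integer.max
    dat <- simulate_individuals(gen_model, gen_params, design, seed = rep_seed)
    agg <- aggregate_observed(dat)
    for (m in methods) {
      d <- if (grepl("_aggregate$", m)) agg else dat
      fit <- tryCatch(
        fit_model(d, ana_model, init, m, design = design, n_sim = n_sim,
                  estimate = estimate, control = control),
        error = function(e) NULL)
      if (is.null(fit)) {
        rows[[length(rows) + 1L]] <-
          data.frame(replicate = r, method = m, parameter = NA_character_,
                     value = NA_real_, converged = FALSE)
      } else {
        vals <- .free_param_values(fit$estimates, fit$transform)
        rows[[length(rows) + 1L]] <-
          data.frame(replicate = r, method = m, parameter = fit$par_names,
                     value = vals, converged = fit$converged)
      }
    }
  }
  est <- do.call(rbind, rows)
  ok <- est[est$converged & !is.na(est$parameter), ]
  summ <- do.call(rbind, lapply(split(ok, list(ok$method, ok$parameter),
                                      drop = TRUE), function(g)
    data.frame(method = g$method[1], parameter = g$parameter[1],
               mean = mean(g$value), sd = stats::sd(g$value),
               n_converged = nrow(g))))
  rownames(summ) <- NULL
  structure(list(estimates = est, summary = summ, seed = seed,
                 n_replicates = n_replicates, gen_model = gen_model$name,
                 ana_model = ana_model$name),
            class = "sse_result")
}

#' @export
print.sse_result <- function(x, ...) {
  cat("SSE:", x$n_replicates, "replicates, generator '", x$gen_model,
      "' -> analyst '", x$ana_model, "'\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
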