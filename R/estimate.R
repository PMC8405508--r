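# Maximum-likelihood fitting of population parameters to individual or
# aggregate data, with log-scale parameter transforms and Hessian-based
# standard errors.

#' Parameter transform between pop_params and an unconstrained vector
#'
#' Positive quantities (fixed effects under the lognormal map, variance
#' terms) are optimized on the log scale. Off-diagonals of omega are not
#' estimated (held at their initial values, zero for all built-in case
#' studies). The estimation mask selects which entries are free.
#'
#' @param init A [pop_params()] providing structure and fixed values.
#' @param model The bound [structural_model()] (its parameter map decides
#'   whether beta is log-transformed).
#' @param estimate Optional list with logical vectors `beta`, `omega_diag`,
#'   and flags `sigma_add2`, `sigma_prop2`. Defaults: estimate all beta, the
#'   positive omega diagonal entries, and each residual variance that is
#'   positive.
#' @return An object of class `param_transform` with `pack` and `unpack`
#'   functions, parameter `names`, and the free-parameter count `n_free`.
#' @export
param_transform <- function(init, model, estimate = NULL) {
  p <- length(init$beta); v <- nrow(init$omega)
  est <- list(beta = rep(TRUE, p),
              omega_diag = diag(init$omega) > 0,
              sigma_add2 = init$sigma_add2 > 0,
              sigma_prop2 = init$sigma_prop2 > 0)
  if (!is.null(estimate)) est[names(estimate)] <- estimate
  log_beta <- model$param_map_kind == "lognormal"
  names <- c(paste0("beta", seq_len(p))[est$beta],
             paste0("omega2_", seq_len(v))[est$omega_diag],
             if (est$sigma_add2) "sigma_add2",
             if (est$sigma_prop2) "sigma_prop2")
  pack <- function(params) {
    b <- params$beta[est$beta]
    c(if (log_beta) log(b) else b,
      log(diag(params$omega)[est$omega_diag]),
      if (est$sigma_add2) log(params$sigma_add2),
      if (est$sigma_prop2) log(params$sigma_prop2))
  }
  unpack <- function(x) {
    beta <- init$beta; omega <- init$omega
    sa <- init$sigma_add2; sp <- init$sigma_prop2
    i <- 0L
    nb <- sum(est$beta)
    if (nb) {
      xb <- x[seq_len(nb)]
      beta[est$beta] <- if (log_beta) exp(xb) else xb
      i <- nb
    }
    no <- sum(est$omega_diag)
    if (no) {
      diag(omega)[est$omega_diag] <- exp(x[i + seq_len(no)])
      i <- i + no
    }
    if (est$sigma_add2) { sa <- exp(x[i + 1L]); i <- i + 1L }
    if (est$sigma_prop2) { sp <- exp(x[i + 1L]) }
    pop_params(beta, omega, sa, sp)
  }
  structure(list(pack = pack, unpack = unpack, names = names,
                 n_free = length(names), estimate = est),
            class = "param_transform")
}

# Builds the (penalized) log-likelihood function of a candidate pop_params
# for a given method. Aggregate non-FO methods hold the quasi-random
# standard-normal points fixed (common random numbers), so the objective is
# deterministic and smooth for the optimizer.
.make_loglik_fn <- function(data, model, method, n_sim, design) {
  agg_methods <- c(fo_aggregate = "fo", foce_aggregate = "foce",
                   focei_aggregate = "focei", mc_aggregate = "mc")
  ind_methods <- c(fo_individual = "fo", foce_individual = "foce",
                   focei_individual = "focei")
  if (method %in% names(ind_methods)) {
    if (!inherits(data, "individual_dataset"))
      stop("individual-data methods require an individual_dataset")
    meth <- ind_methods[[method]]
    fn <- function(params) loglik_individual(data, model, params, meth)$loglik
    return(list(fn = fn, n_sim = 1L))
  }
  if (!method %in% names(agg_methods)) stop("unknown method: ", method)
  if (inherits(data, "individual_dataset")) data <- aggregate_observed(data)
  if (!inherits(data, "aggregate_data"))
    stop("aggregate methods require aggregate_data or an individual_dataset")
  approx <- agg_methods[[method]]
  if (approx == "fo") {
    fn <- function(params)
      loglik_aggregate(data, expected_moments(model, params, design, "fo"))
    return(list(fn = fn, n_sim = 1L))
  }
  if (is.null(n_sim)) n_sim <- max(300L, data$n_subjects)
  sample <- sample_random_effects(diag(model$v), n_sim, "sobol")
  fn <- function(params)
    loglik_aggregate(data, expected_moments(model, params, design, approx,
                                            sample = sample))
  list(fn = fn, n_sim = as.integer(n_sim))
}

#' Fit a population PK model by maximum likelihood
#'
#' Maximizes the selected log-likelihood over the transformed parameter
#' space: a derivative-free Nelder-Mead stage followed by a quasi-Newton
#' (BFGS) polish. Aggregate FOCE/MC methods fix one Sobol sample per fit and
#' re-scale it to each candidate omega, keeping the objective deterministic.
#'
#' @param data An [individual_dataset()] or [aggregate_data()]. Individual
#'   data supplied to an aggregate method are aggregated first.
#' @param model A [structural_model()].
#' @param init Initial [pop_params()].
#' @param method One of "fo_individual", "foce_individual",
#'   "focei_individual", "fo_aggregate", "foce_aggregate",
#'   "focei_aggregate", "mc_aggregate".
#' @param design The [pk_design()]; may be omitted when `data` is an
#'   individual dataset (taken from it).
#' @param n_sim Quasi-Monte-Carlo sample size for aggregate FOCE/MC methods;
#'   default `max(300, N)`.
#' @param estimate Estimation mask, see [param_transform()].
#' @param control List of optimizer settings: `simplex_maxit` (default 500),
#'   `bfgs_maxit` (default 200), `reltol` (default 1e-10), `skip_simplex`
#'   (default FALSE, skip the Nelder-Mead stage), `search_radius` (default
#'   9, half-width of the box around the start on the transformed scale
#'   beyond which a smooth quadratic barrier applies), `fo_prestart`
#'   (default TRUE: aggregate FOCE/MC fits are staged from a preliminary
#'   FO-aggregate fit of the same data, the standard staged-estimation
#'   workflow; the quasi-Monte-Carlo objectives are only trustworthy near
#'   parameter regions their fixed sample resolves).
#' @param compute_se Attach Hessian-based standard errors (default FALSE).
#' @return An object of class `fit_result`.
#' @export
fit_model <- function(data, model, init, method, design = NULL, n_sim = NULL,
                      estimate = NULL, control = list(), compute_se = FALSE) {
  .check_params_model(init, model)
  if (is.null(design)) {
    if (inherits(data, "individual_dataset")) design <- data$design
    else stop("design must be supplied with aggregate_data input")
  }
  ctl <- utils::modifyList(list(simplex_maxit = 500, bfgs_maxit = 200,
                                reltol = 1e-10, skip_simplex = FALSE,
                                search_radius = 9, fo_prestart = TRUE), control)
  if (ctl$fo_prestart &&
      method %in% c("foce_aggregate", "focei_aggregate", "mc_aggregate")) {
    pre <- tryCatch(
      fit_model(data, model, init, "fo_aggregate", design = design,
                estimate = estimate,
                control = utils::modifyList(ctl, list(fo_prestart = FALSE))),
      error = function(e) NULL)
    if (!is.null(pre) && pre$converged) init <- pre$estimates
  }
  tr <- param_transform(init, model, estimate)
  lk <- .make_loglik_fn(data, model, method, n_sim, design)
  x0 <- tr$pack(init)
  # Smooth quadratic barrier beyond a wide box around the start (default
  # e^+-9, about four orders of magnitude each way). Far outside that box
  # the finite-sample quasi-MC objectives develop spurious optima (the
  # integrand turns heavy-tailed and a fixed Sobol sample no longer
  # resolves it), so the search is kept inside the meaningful region.
  lower <- x0 - ctl$search_radius; upper <- x0 + ctl$search_radius
  nev <- 0L
  negll <- function(x) {
    nev <<- nev + 1L
    barrier <- 1e4 * sum(pmax(0, x - upper)^2 + pmax(0, lower - x)^2)
    p <- tryCatch(tr$unpack(x), error = function(e) NULL)
    if (is.null(p)) return(-.PENALTY + barrier)
    val <- tryCatch(lk$fn(p), error = function(e) NA_real_)
    if (!is.finite(val)) return(-.PENALTY + barrier)
    -val + barrier
  }
  if (!ctl$skip_simplex && tr$n_free > 1) {
    s1 <- stats::optim(x0, negll, method = "Nelder-Mead",
                       control = list(maxit = ctl$simplex_maxit,
                                      reltol = ctl$reltol))
    x0 <- s1$par
  }
  s2 <- stats::optim(x0, negll, method = "BFGS",
                     control = list(maxit = ctl$bfgs_maxit,
                                    reltol = ctl$reltol))
  est <- tr$unpack(s2$par)
  ll <- -s2$value
  res <- structure(list(method = method, estimates = est, loglik = ll,
                        ofv = ofv(ll), converged = s2$convergence == 0,
                        n_evals = nev, n_sim = lk$n_sim, se = NULL,
                        rse_percent = NULL, transform = tr,
                        par_names = tr$names, design = design),
                   class = "fit_result")
  if (compute_se) res <- standard_errors(res, data, model)
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit (", x$method, "): OFV = ", format(x$ofv, digits = 8),
      ", converged = ", x$converged, ", evaluations = ", x$n_evals, "\n",
      sep = "")
  tab <- coef_table(x)
  print(tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Tabulate estimates of a fit
#'
#' @param fit A `fit_result`.
#' @return Data frame with parameter names, estimates and (when computed)
#'   standard errors and RSE%.
#' @export
coef_table <- function(fit) {
  est <- .free_param_values(fit$estimates, fit$transform)
  tab <- data.frame(parameter = fit$par_names, estimate = est)
  if (!is.null(fit$se)) {
    tab$se <- fit$se
    tab$rse_percent <- fit$rse_percent
  }
  tab
}

# Natural-scale values of the free parameters, in transform order.
.free_param_values <- function(params, tr) {
  est <- tr$estimate
  c(params$beta[est$beta], diag(params$omega)[est$omega_diag],
    if (est$sigma_add2) params$sigma_add2,
    if (est$sigma_prop2) params$sigma_prop2)
}

# Rebuild pop_params from natural-scale free values (for numerical
# derivatives on the reported scale).
.params_from_free <- function(x, init, tr) {
  est <- tr$estimate
  beta <- init$beta; omega <- init$omega
  sa <- init$sigma_add2; sp <- init$sigma_prop2
  i <- 0L
  nb <- sum(est$beta)
  if (nb) { beta[est$beta] <- x[seq_len(nb)]; i <- nb }
  no <- sum(est$omega_diag)
  if (no) { diag(omega)[est$omega_diag] <- x[i + seq_len(no)]; i <- i + no }
  if (est$sigma_add2) { sa <- x[i + 1L]; i <- i + 1L }
  if (est$sigma_prop2) sp <- x[i + 1L]
  pop_params(beta, omega, sa, sp)
}

#' Standard errors from the observed information
#'
#' Central-difference Hessian of the negative log-likelihood at the
#' estimates, on the natural (untransformed) parameter scale, inverted to a
#' covariance matrix. RSE% is `100 * se / |estimate|`. When the Hessian is
#' not invertible the SEs are absent and `se_ok` is FALSE.
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param data The data the fit used.
#' @param model The model the fit used.
#' @return The fit with `se`, `rse_percent` and `se_ok` filled in.
#' @export
standard_errors <- function(fit, data, model) {
  lk <- .make_loglik_fn(data, model, fit$method, fit$n_sim, fit$design)
  tr <- fit$transform
  x <- .free_param_values(fit$estimates, tr)
  fn <- function(z) {
    p <- tryCatch(.params_from_free(z, fit$estimates, tr),
                  error = function(e) NULL)
    if (is.null(p)) return(-.PENALTY)
    val <- tryCatch(lk$fn(p), error = function(e) NA_real_)
    if (!is.finite(val)) return(-.PENALTY)
    -val
  }
  H <- num_hessian(fn, x)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    fit$se <- NULL; fit$rse_percent <- NULL; fit$se_ok <- FALSE
  } else {
    fit$se <- sqrt(diag(cov))
    fit$rse_percent <- 100 * fit$se / abs(x)
    fit$se_ok <- TRUE
  }
  fit
}
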