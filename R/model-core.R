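#' Population parameter set for a nonlinear mixed-effects model
#'
#' Bundles the full parameter vector of a population PK model: the fixed
#' effects `beta` (typical-subject parameters), the random-effect covariance
#' matrix `omega` (log-scale variances under the default lognormal parameter
#' map), and the residual-error variances. Either residual variance may be
#' zero, but not both.
#'
#' @param beta Numeric vector of fixed effects (model-specific units, e.g.
#'   clearance in L/h, volumes in L).
#' @param omega Random-effect covariance matrix (v x v), or a numeric vector
#'   taken as its diagonal. Must be symmetric positive semi-definite.
#' @param sigma_add2 Additive residual variance, (mg/L)^2. Default 0.
#' @param sigma_prop2 Proportional residual variance (dimensionless).
#'   Default 0.
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(beta, omega, sigma_add2 = 0, sigma_prop2 = 0) {
  beta <- stats::setNames(as.numeric(beta), names(beta))
  if (is.null(dim(omega))) omega <- diag(as.numeric(omega), nrow = length(omega))
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) stop("omega must be square")
  if (max(abs(omega - t(omega))) > 1e-8 * max(1, max(abs(omega))))
    stop("omega must be symmetric")
  omega <- (omega + t(omega)) / 2
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("omega is not positive semi-definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (sigma_add2 < 0 || sigma_prop2 < 0) stop("residual variances must be >= 0")
  if (sigma_add2 == 0 && sigma_prop2 == 0)
    stop("at least one residual variance must be > 0")
  structure(list(beta = beta, omega = omega,
                 sigma_add2 = as.numeric(sigma_add2),
                 sigma_prop2 = as.numeric(sigma_prop2)),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population parameters\n")
  cat("  beta       :", paste(signif(x$beta, 6), collapse = ", "), "\n")
  cat("  omega diag :", paste(signif(diag(x$omega), 6), collapse = ", "), "\n")
  if (any(x$omega[upper.tri(x$omega)] != 0))
    cat("  omega has nonzero off-diagonals\n")
  cat("  sigma_add2 :", x$sigma_add2, "  sigma_prop2 :", x$sigma_prop2, "\n")
  invisible(x)
}

#' Elementary design: sampling schedule, dose and group size
#'
#' A single-group design shared by `n_subjects` subjects: one dose and a
#' common vector of sampling times. The observation vector for one subject
#' has one slot per sampling time (single-response PK).
#'
#' @param times Numeric vector of sampling times (h), non-negative and
#'   non-decreasing.
#' @param dose_amount Dose (mg), >= 0. Default 100.
#' @param dose_time Dosing time (h). Default 0.
#' @param n_subjects Number of subjects sharing this design, >= 1.
#' @return An object of class `pk_design`.
#' @export
pk_design <- function(times, dose_amount = 100, dose_time = 0, n_subjects = 1) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (dose_amount < 0) stop("dose_amount must be >= 0")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(times = times, dose_amount = dose_amount,
                 dose_time = dose_time, n_subjects = n_subjects),
            class = "pk_design")
}

#' @export
print.pk_design <- function(x, ...) {
  cat("Design:", length(x$times), "sampling times (",
      paste(x$times, collapse = ", "), ") h;",
      x$dose_amount, "mg at t =", x$dose_time, "h;",
      x$n_subjects, "subjects\n")
  invisible(x)
}

#' Structural model contract
#'
#' A structural model is the triplet (f, h, g): the structural prediction
#' `predict`, the residual-error model kind, and the individual-parameter
#' map kind. `predict` must accept an n x n_theta matrix of individual
#' parameter vectors (one per row) and a design, and return the n x K matrix
#' of predictions, K being the number of sampling times.
#'
#' @param name Identifier string.
#' @param n_theta Number of individual parameters.
#' @param v Number of random effects (equal to `n_theta` for the built-in
#'   models; inactive effects carry a zero variance in omega).
#' @param predict Function `(theta_matrix, design) -> prediction matrix`.
#' @param residual_kind One of "additive", "proportional", "combined".
#' @param param_map_kind One of "lognormal", "identity".
#' @return An object of class `structural_model`.
#' @seealso [pk_model()] for the built-in models.
#' @export
structural_model <- function(name, n_theta, v, predict,
                             residual_kind = c("additive", "proportional", "combined"),
                             param_map_kind = c("lognormal", "identity")) {
  residual_kind <- match.arg(residual_kind)
  param_map_kind <- match.arg(param_map_kind)
  stopifnot(is.function(predict), n_theta >= 1, v >= 1)
  structure(list(name = name, n_theta = as.integer(n_theta), v = as.integer(v),
                 predict = predict, residual_kind = residual_kind,
                 param_map_kind = param_map_kind),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Structural model '", x$name, "': ", x$n_theta, " parameters, ",
      x$v, " random effects, ", x$residual_kind, " error, ",
      x$param_map_kind, " parameter map\n", sep = "")
  invisible(x)
}

#' Individual-parameter map g(beta, b)
#'
#' Maps fixed effects and a subject's random-effect vector to the subject's
#' individual parameters. The lognormal map is `theta = beta * exp(b)`
#' elementwise (the field's default for strictly positive PK parameters);
#' the identity map is `theta = beta + b`. Both satisfy `g(beta, 0) = beta`.
#'
#' @param beta Fixed-effect vector.
#' @param b Random-effect vector of the same length, or an n x v matrix of
#'   random-effect vectors (one subject per row).
#' @param kind "lognormal" or "identity".
#' @return Individual parameter vector, or n x v matrix if `b` is a matrix.
#' @export
param_map <- function(beta, b, kind = c("lognormal", "identity")) {
  kind <- match.arg(kind)
  if (is.matrix(b)) {
    if (ncol(b) != length(beta)) stop("ncol(b) must equal length(beta)")
    if (kind == "lognormal") {
      if (any(beta <= 0)) stop("lognormal map requires beta > 0")
      exp(b) %*% diag(beta, length(beta))
    } else {
      sweep(b, 2, beta, "+")
    }
  } else {
    if (length(b) != length(beta)) stop("length(b) must equal length(beta)")
    if (kind == "lognormal") {
      if (any(beta <= 0)) stop("lognormal map requires beta > 0")
      beta * exp(b)
    } else beta + b
  }
}

# Bi-exponential disposition constants for the two-compartment model.
# Returns list of vectors alpha, beta (alpha >= beta) for vectors of
# micro-constants; a vanishing discriminant is lifted by a relative nudge
# of k21 (equal disposition eigenvalues are a measure-zero degeneracy).
.disposition_roots <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  disc2 <- s^2 - 4 * k10 * k21
  bad <- disc2 < 1e-18 * s^2
  if (any(bad)) {
    k21[bad] <- k21[bad] * (1 + 1e-8)
    s <- k10 + k12 + k21
    disc2 <- s^2 - 4 * k10 * k21
  }
  disc <- sqrt(pmax(disc2, 0))
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = k21)
}

# Closed-form two-compartment first-order-absorption concentration profile.
# theta: n x 5 matrix (CL, Vc, Vp, Q, ka); returns n x K (mg/L).
.predict_twocomp <- function(theta, design) {
  CL <- theta[, 1]; Vc <- theta[, 2]; Vp <- theta[, 3]
  Q <- theta[, 4]; ka <- theta[, 5]
  if (any(theta <= 0)) stop("two-compartment model requires positive parameters")
  r <- .disposition_roots(CL / Vc, Q / Vc, Q / Vp)
  al <- r$alpha; be <- r$beta; k21 <- r$k21
  # ka coinciding with a disposition root makes the tri-exponential
  # degenerate; resolved by a 1e-10 relative perturbation of ka
  clash <- pmin(abs(ka - al), abs(ka - be)) < 1e-9 * ka
  if (any(clash)) ka[clash] <- ka[clash] * (1 + 1e-10)
  A <- (k21 - al) / ((ka - al) * (be - al))
  B <- (k21 - be) / ((ka - be) * (al - be))
  C <- (k21 - ka) / ((al - ka) * (be - ka))
  tp <- pmax(design$times - design$dose_time, 0)
  scale <- ka * design$dose_amount / Vc
  conc <- scale * (A * exp(-outer(al, tp)) + B * exp(-outer(be, tp)) +
                   C * exp(-outer(ka, tp)))
  conc[, design$times < design$dose_time] <- 0
  conc
}

# Transit-compartment absorption (2 transit compartments) over the same
# disposition. Chain depot -> transit1 -> transit2 -> central, each step at
# rate ktr = (n_transit + 1)/MTT = 3/MTT, i.e. Erlang-3 input to central,
# convolved in closed form with the bi-exponential disposition.
# theta: n x 5 matrix (MTT, CL, Vc, Vp, Q); returns n x K (mg/L).
.predict_transit2 <- function(theta, design) {
  MTT <- theta[, 1]; CL <- theta[, 2]; Vc <- theta[, 3]
  Vp <- theta[, 4]; Q <- theta[, 5]
  if (any(theta <= 0)) stop("transit model requires positive parameters")
  ktr <- 3 / MTT
  r <- .disposition_roots(CL / Vc, Q / Vc, Q / Vp)
  al <- r$alpha; be <- r$beta; k21 <- r$k21
  clash <- pmin(abs(ktr - al), abs(ktr - be)) < 1e-9 * ktr
  if (any(clash)) ktr[clash] <- ktr[clash] * (1 + 1e-10)
  ca <- (k21 - al) / (be - al)
  cb <- (k21 - be) / (al - be)
  tp <- pmax(design$times - design$dose_time, 0)
  # integral of s^2 exp(-mu s) over (0, t], times exp(-lambda t), for the
  # Erlang-3 convolution; mu = ktr - lambda
  conv <- function(lam) {
    mu <- ktr - lam
    tm <- outer(mu, tp)
    exp(-outer(lam, tp)) * (2 - exp(-tm) * (tm^2 + 2 * tm + 2)) / mu^3
  }
  amt <- (design$dose_amount * ktr^3 / 2) * (ca * conv(al) + cb * conv(be))
  conc <- amt / Vc
  conc[, design$times < design$dose_time] <- 0
  conc
}

# Wang one-compartment decay y = 10 exp(-theta t); the amplitude 10 is part
# of the cited model, not the dose. theta: n x 1 matrix; returns n x K.
.predict_wang <- function(theta, design) {
  th <- theta[, 1]
  if (any(th <= 0)) stop("wang model requires theta > 0")
  if (any(design$times < 0)) stop("negative times")
  10 * exp(-outer(th, design$times))
}

#' Built-in structural PK models
#'
#' Returns one of the registered structural models by name:
#' \describe{
#'   \item{"wang"}{One-compartment exponential decay `f = 10 exp(-theta t)`
#'     with a single lognormal random effect, the classical worked example
#'     for comparing NONMEM-type objective functions.}
#'   \item{"twocomp_oral"}{Two-compartment mammillary model with first-order
#'     absorption and elimination; parameters (CL, Vc, Vp, Q, ka), lognormal
#'     random effect on each. Concentration is the central amount over Vc.}
#'   \item{"transit2"}{Transit-compartment absorption with 2 transit
#'     compartments over the same disposition; parameters
#'     (MTT, CL, Vc, Vp, Q), transit rate `ktr = 3/MTT` with the depot
#'     counted in the chain.}
#' }
#'
#' @param name Model name.
#' @param residual_kind Residual-error model; defaults to "additive".
#' @return A [structural_model()].
#' @export
pk_model <- function(name = c("wang", "twocomp_oral", "transit2"),
                     residual_kind = c("additive", "proportional", "combined")) {
  name <- match.arg(name)
  residual_kind <- match.arg(residual_kind)
  switch(name,
    wang = structural_model("wang", 1, 1, .predict_wang, residual_kind,
                            "lognormal"),
    twocomp_oral = structural_model("twocomp_oral", 5, 5, .predict_twocomp,
                                    residual_kind, "lognormal"),
    transit2 = structural_model("transit2", 5, 5, .predict_transit2,
                                residual_kind, "lognormal"))
}

#' Evaluate a structural model
#'
#' Convenience wrapper around the model's `predict` slot accepting either a
#' single parameter vector or a matrix of parameter vectors.
#'
#' @param model A [structural_model()].
#' @param theta Parameter vector (length `n_theta`) or n x n_theta matrix.
#' @param design A [pk_design()].
#' @return Length-K prediction vector, or n x K matrix if `theta` is a matrix.
#' @export
predict_model <- function(model, theta, design) {
  if (is.matrix(theta)) {
    if (ncol(theta) != model$n_theta) stop("theta has wrong length")
    model$predict(theta, design)
  } else {
    if (length(theta) != model$n_theta) stop("theta has wrong length")
    drop(model$predict(matrix(theta, nrow = 1), design))
  }
}

#' Per-observation residual variances
#'
#' The diagonal of the linearized residual covariance
#' `diag(J_h Sigma J_h')` at epsilon = 0: `sigma_add2` for additive error,
#' `f^2 * sigma_prop2` for proportional, and their sum for combined.
#'
#' @param f_pred Prediction vector or matrix.
#' @param params A [pop_params()].
#' @param kind Residual-error kind (usually the model's `residual_kind`).
#' @return Residual variance of the same shape as `f_pred`.
#' @export
residual_variances <- function(f_pred, params,
                               kind = c("additive", "proportional", "combined")) {
  kind <- match.arg(kind)
  switch(kind,
    additive = 0 * f_pred + params$sigma_add2,
    proportional = f_pred^2 * params$sigma_prop2,
    combined = f_pred^2 * params$sigma_prop2 + params$sigma_add2)
}

# Validates that params and model dimensions agree.
.check_params_model <- function(params, model) {
  if (length(params$beta) != model$n_theta)
    stop("length(beta) does not match model n_theta")
  if (nrow(params$omega) != model$v)
    stop("omega dimension does not match model v")
  if (model$residual_kind == "additive" && params$sigma_add2 <= 0)
    stop("additive residual model requires sigma_add2 > 0")
  if (model$residual_kind == "proportional" && params$sigma_prop2 <= 0)
    stop("proportional residual model requires sigma_prop2 > 0")
  invisible(TRUE)
}
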