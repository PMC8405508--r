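# Shared builders for the case-study settings used across the tests.

case2_params <- function() pop_params(c(5, 10, 30, 10, 1), rep(0.3^2, 5),
                                      sigma_add2 = 0.2^2)

case2_design <- function(n = 100) pk_design(c(0.1, 0.25, 0.5, 1, 2, 3, 5, 8, 12),
                                            dose_amount = 100, dose_time = 0,
                                            n_subjects = n)

case4_gen_params <- function() pop_params(c(1, 5, 10, 30, 10),
                                          c(0.3^2, 0, 0, 0, 0),
                                          sigma_add2 = 0.2^2)

wang_params <- function(proportional = FALSE) {
  if (proportional) pop_params(0.5, 0.04, sigma_prop2 = 0.1)
  else pop_params(0.5, 0.04, sigma_add2 = 0.1)
}

wang_data <- function() {
  read_observations_csv(system.file("extdata", "wang2007.csv",
                                    package = "aggpk"))
}

# Numerical ODE solution of the built-in compartmental models (independent
# oracle for the closed-form predictions).
ode_twocomp <- function(theta, design) {
  CL <- theta[1]; Vc <- theta[2]; Vp <- theta[3]; Q <- theta[4]; ka <- theta[5]
  rhs <- function(t, y, p) list(c(-ka * y[1],
                                  ka * y[1] - (CL / Vc + Q / Vc) * y[2] + (Q / Vp) * y[3],
                                  (Q / Vc) * y[2] - (Q / Vp) * y[3]))
  out <- deSolve::ode(c(design$dose_amount, 0, 0), c(0, design$times), rhs,
                      NULL, rtol = 1e-12, atol = 1e-12)
  out[-1, 3] / Vc
}

ode_transit2 <- function(theta, design) {
  MTT <- theta[1]; CL <- theta[2]; Vc <- theta[3]; Vp <- theta[4]; Q <- theta[5]
  ktr <- 3 / MTT
  rhs <- function(t, y, p) list(c(-ktr * y[1],
                                  ktr * (y[1] - y[2]),
                                  ktr * (y[2] - y[3]),
                                  ktr * y[3] - (CL / Vc + Q / Vc) * y[4] + (Q / Vp) * y[5],
                                  (Q / Vc) * y[4] - (Q / Vp) * y[5]))
  out <- deSolve::ode(c(design$dose_amount, 0, 0, 0, 0), c(0, design$times),
                      rhs, NULL, rtol = 1e-12, atol = 1e-12)
  out[-1, 5] / Vc
}

free_values <- function(fit) aggpk:::.free_param_values(fit$estimates,
                                                        fit$transform)
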