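test_that("parameter map satisfies g(beta, 0) = beta and the lognormal form", {
  beta <- c(5, 10, 30, 10, 1)
  expect_identical(param_map(beta, rep(0, 5), "lognormal"), beta)
  expect_identical(param_map(beta, rep(0, 5), "identity"), beta)
  expect_equal(param_map(0.5, 0, "lognormal"), 0.5)
  expect_equal(param_map(5, 0.3, "lognormal"), 5 * exp(0.3), tolerance = 1e-12)
  expect_equal(param_map(5, 0.3, "identity"), 5.3)
  # matrix form agrees with row-wise evaluation
  B <- matrix(c(0.1, -0.2, 0, 0.3, -0.1, 0.2, 0.05, 0, -0.3, 0.1), 2, 5)
  th <- param_map(beta, B, "lognormal")
  expect_equal(th[2, ], param_map(beta, B[2, ], "lognormal"))
  expect_error(param_map(c(-1, 2), c(0, 0), "lognormal"), "beta > 0")
  expect_error(param_map(beta, c(0, 0)), "length")
})

test_that("Wang decay model evaluates 10 exp(-theta t) and rejects bad input", {
  m <- pk_model("wang")
  d <- pk_design(c(0, 1, 2, 5), n_subjects = 1)
  f <- predict_model(m, 0.5, d)
  expect_equal(f[1], 10)
  expect_equal(f[2], 10 * exp(-0.5), tolerance = 1e-12)
  expect_true(all(diff(f) < 0))
  expect_lt(predict_model(m, 0.5, pk_design(50))[1], 1e-9)
  expect_error(predict_model(m, -0.5, d), "theta > 0")
})

test_that("closed-form two-compartment oral model matches an ODE solve to 1e-8", {
  skip_if_not_installed("deSolve")
  m <- pk_model("twocomp_oral")
  d <- case2_design(1)
  for (th in list(c(5, 10, 30, 10, 1), c(2, 8, 100, 25, 0.4),
                  c(12, 40, 15, 3, 3.5))) {
    f <- predict_model(m, th, d)
    o <- ode_twocomp(th, d)
    expect_lt(max(abs(f - o) / o), 1e-8)
  }
})

test_that("two-compartment model is zero at dose time and handles rate clashes", {
  m <- pk_model("twocomp_oral")
  d <- pk_design(c(0, 0.5, 2), dose_amount = 100, dose_time = 0, n_subjects = 1)
  f <- predict_model(m, c(5, 10, 30, 10, 1), d)
  expect_equal(f[1], 0)
  # ka equal to a disposition eigenvalue: the perturbed evaluation stays
  # finite and close to nearby ka values
  th <- c(5, 10, 30, 10, 1)
  k10 <- th[1] / th[2]; k12 <- th[4] / th[2]; k21 <- th[4] / th[3]
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  th_clash <- c(th[1:4], alpha)
  f_clash <- predict_model(m, th_clash, case2_design(1))
  f_near <- predict_model(m, c(th[1:4], alpha * (1 + 1e-7)), case2_design(1))
  expect_true(all(is.finite(f_clash)))
  expect_lt(max(abs(f_clash - f_near) / f_near), 1e-4)
})

test_that("closed linear system conserves mass in its ODE representation", {
  skip_if_not_installed("deSolve")
  th <- c(5, 10, 30, 10, 1)
  CL <- th[1]; Vc <- th[2]; Vp <- th[3]; Q <- th[4]; ka <- th[5]
  rhs <- function(t, y, p) list(c(-ka * y[1],
                                  ka * y[1] - (CL / Vc + Q / Vc) * y[2] + (Q / Vp) * y[3],
                                  (Q / Vc) * y[2] - (Q / Vp) * y[3],
                                  (CL / Vc) * y[2]))
  out <- deSolve::ode(c(100, 0, 0, 0), c(0, 1, 4, 12), rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  expect_equal(rowSums(out[, -1]), rep(100, 4), tolerance = 1e-9)
})

test_that("transit-absorption model matches an ODE solve and delays the peak", {
  skip_if_not_installed("deSolve")
  m <- pk_model("transit2")
  d <- case2_design(1)
  for (th in list(c(1, 5, 10, 30, 10), c(0.3, 2, 8, 100, 25),
                  c(2.5, 12, 40, 15, 3))) {
    f <- predict_model(m, th, d)
    o <- ode_transit2(th, d)
    expect_lt(max(abs(f - o) / o), 1e-8)
    expect_true(all(f >= 0))
  }
  expect_equal(predict_model(m, c(1, 5, 10, 30, 10),
                             pk_design(0, n_subjects = 1)), 0)
  # the transit chain shifts absorption later than first-order ka = 1
  grid <- pk_design(seq(0.05, 6, by = 0.05), n_subjects = 1)
  f_tr <- predict_model(m, c(1, 5, 10, 30, 10), grid)
  f_ka <- predict_model(pk_model("twocomp_oral"), c(5, 10, 30, 10, 1), grid)
  expect_gt(grid$times[which.max(f_tr)], grid$times[which.max(f_ka)])
})

test_that("residual variances follow the additive/proportional/combined forms", {
  p <- pop_params(1, 0.04, sigma_add2 = 0.04, sigma_prop2 = 0.01)
  f <- c(0, 2, 10)
  expect_equal(residual_variances(f, p, "additive"), rep(0.04, 3))
  expect_equal(residual_variances(f, p, "proportional"), c(0, 0.04, 1))
  expect_equal(residual_variances(f, p, "combined"), c(0.04, 0.08, 1.04))
})

test_that("parameter containers validate their invariants", {
  expect_error(pop_params(1, matrix(c(1, 0.5, 0.4, 1), 2), sigma_add2 = 1),
               "symmetric")
  expect_error(pop_params(1, -0.1, sigma_add2 = 1), "positive semi-definite")
  expect_error(pop_params(1, 0.1), "at least one residual variance")
  expect_error(pk_design(c(2, 1)), "non-decreasing")
  expect_error(pk_design(-1), "non-negative")
  expect_error(pk_design(1, n_subjects = 0), "n_subjects")
  # singular omega (zero-variance effects) is legal
  p <- pop_params(c(1, 2), c(0.09, 0), sigma_add2 = 0.01)
  expect_equal(diag(p$omega), c(0.09, 0))
})
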