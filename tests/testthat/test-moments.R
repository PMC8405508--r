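test_that("random-effect Jacobian matches the analytic derivative", {
  # Wang model, lognormal map: df/db = -10 t theta exp(-theta t) at b = 0
  m <- pk_model("wang")
  p <- wang_params()
  d <- pk_design(c(0, 1), n_subjects = 1)
  J <- jacobian_re(m, p, 0, d)
  expect_equal(dim(J), c(2, 1))
  expect_equal(J[1, 1], 0, tolerance = 1e-8)
  expect_equal(J[2, 1], -10 * 0.5 * exp(-0.5), tolerance = 1e-8)
  # linear model with identity map: the Jacobian column is exactly t
  lin <- structural_model("lin", 1, 1,
                          function(theta, design) theta %*% rbind(design$times),
                          "additive", "identity")
  Jl <- jacobian_re(lin, pop_params(2, 1, sigma_add2 = 1), 0.7,
                    pk_design(c(1, 3), n_subjects = 1))
  expect_equal(Jl[, 1], c(1, 3), tolerance = 1e-9)
})

test_that("finite-difference Jacobian error shrinks quadratically with the step", {
  m <- pk_model("twocomp_oral")
  p <- case2_params()
  d <- case2_design(1)
  b <- c(0.1, -0.2, 0.05, 0.15, -0.1)
  fd <- function(h) {
    J <- matrix(0, 9, 5)
    for (j in 1:5) {
      bp <- b; bp[j] <- b[j] + h
      bm <- b; bm[j] <- b[j] - h
      J[, j] <- (predict_model(m, param_map(p$beta, bp), d) -
                 predict_model(m, param_map(p$beta, bm), d)) / (2 * h)
    }
    J
  }
  ref <- fd(1e-6)
  e1 <- max(abs(fd(4e-3) - ref))
  e2 <- max(abs(fd(2e-3) - ref))
  expect_gt(e1 / e2, 3)  # central differences: error ~ h^2
})

test_that("FO moments reproduce the hand-evaluated Wang case", {
  m <- pk_model("wang")
  p <- wang_params()
  d <- pk_design(c(0, 1), n_subjects = 1)
  mom <- expected_moments(m, p, d, "fo")
  expect_equal(mom$ytilde, c(10, 10 * exp(-0.5)), tolerance = 1e-10)
  g <- -10 * 0.5 * exp(-0.5)
  expect_equal(mom$Vtilde[2, 2], g^2 * 0.04 + 0.1, tolerance = 1e-7)
  # off-diagonal carries no residual contribution
  expect_equal(mom$Vtilde[1, 2], 0 * g * 0.04, tolerance = 1e-7)
  # no IIV: covariance is the diagonal residual matrix
  m0 <- expected_moments(m, pop_params(0.5, 0, sigma_add2 = 0.1), d, "fo")
  expect_equal(m0$Vtilde, diag(0.1, 2))
  expect_equal(m0$ytilde, mom$ytilde)
})

test_that("FOCE and MC moments collapse to FO without random effects", {
  m <- pk_model("twocomp_oral")
  p <- pop_params(c(5, 10, 30, 10, 1), rep(0, 5), sigma_add2 = 0.04)
  d <- case2_design(1)
  fo <- expected_moments(m, p, d, "fo")
  for (a in c("foce", "focei", "mc")) {
    mom <- expected_moments(m, p, d, a, n_sim = 16)
    expect_equal(mom$ytilde, fo$ytilde, tolerance = 1e-10)
    expect_equal(mom$Vtilde, fo$Vtilde, tolerance = 1e-10)
  }
})

test_that("for a model linear in b the FOCE mean equals the FO mean exactly", {
  lin <- structural_model("lin", 1, 1,
                          function(theta, design) theta %*% rbind(design$times),
                          "additive", "identity")
  p <- pop_params(2, 0.5, sigma_add2 = 0.1)
  d <- pk_design(c(1, 2, 4), n_subjects = 1)
  fo <- expected_moments(lin, p, d, "fo")
  foce <- expected_moments(lin, p, d, "foce", n_sim = 33)
  mc <- expected_moments(lin, p, d, "mc", n_sim = 4096)
  expect_equal(foce$ytilde, fo$ytilde, tolerance = 1e-7)
  expect_equal(foce$Vtilde, fo$Vtilde, tolerance = 1e-7)
  # linearization is exact, so MC agrees in the large-sample limit
  expect_equal(mc$ytilde, fo$ytilde, tolerance = 1e-3)
  expect_equal(mc$Vtilde, fo$Vtilde, tolerance = 1e-2)
})

test_that("MC moments converge to the closed-form lognormal moments", {
  # f = theta at a single slot, theta = 5 exp(b), omega^2 = 0.09,
  # additive sigma^2 = 0.04: mean 5 e^{0.045}, variance
  # 25 e^{0.09}(e^{0.09} - 1) + 0.04
  mod <- structural_model("scalar", 1, 1,
                          function(theta, design) theta,
                          "additive", "lognormal")
  p <- pop_params(5, 0.09, sigma_add2 = 0.04)
  d <- pk_design(0, n_subjects = 1)
  true_mean <- 5 * exp(0.045)
  true_var <- 25 * exp(0.09) * (exp(0.09) - 1) + 0.04
  mom <- expected_moments(mod, p, d, "mc", n_sim = 8192)
  expect_equal(mom$ytilde, true_mean, tolerance = 0.01)
  expect_equal(mom$Vtilde[1, 1], true_var, tolerance = 0.01)
  # quasi-MC error shrinks with sample size
  err <- function(n) {
    m <- expected_moments(mod, p, d, "mc", n_sim = n)
    abs(m$ytilde - true_mean) / true_mean
  }
  expect_lt(err(16384), err(128))
})

test_that("moment matrices are symmetric and gain sigma_add2 on the spectrum", {
  m <- pk_model("twocomp_oral")
  p <- case2_params()
  d <- case2_design(1)
  for (a in c("fo", "foce", "focei", "mc")) {
    mom <- expected_moments(m, p, d, a, n_sim = 64)
    expect_equal(mom$Vtilde, t(mom$Vtilde))
    expect_gte(min(eigen(mom$Vtilde, symmetric = TRUE)$values),
               p$sigma_add2 - 1e-10)
  }
})

test_that("FOCE moments are stable in the quasi-MC sample size", {
  m <- pk_model("twocomp_oral")
  p <- case2_params()
  d <- case2_design(1)
  a <- expected_moments(m, p, d, "foce", n_sim = 300)
  b <- expected_moments(m, p, d, "foce", n_sim = 3000)
  expect_lt(max(abs(a$ytilde - b$ytilde) / b$ytilde), 0.02)
  expect_lt(max(abs(diag(a$Vtilde) - diag(b$Vtilde)) / diag(b$Vtilde)), 0.02)
})
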