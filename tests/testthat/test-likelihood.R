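test_that("quadratic form equals the trace identity on random instances", {
  set.seed(41)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    r <- rnorm(K)
    A <- matrix(rnorm(K * K), K)
    V <- crossprod(A) + diag(0.1, K)
    R <- tcrossprod(r)
    q1 <- drop(r %*% solve(V) %*% r)
    q2 <- sum(diag(R %*% solve(V)))
    expect_equal(q1, q2, tolerance = 1e-10)
  }
})

test_that("Wang dataset reproduces the published FO objective function values", {
  dat <- wang_data()
  agg <- aggregate_observed(dat)
  m <- pk_model("wang")
  p <- wang_params()
  # individual-data and aggregate-data FO are identical, additive error
  o_ind <- ofv(loglik_individual(dat, m, p, "fo")$loglik)
  o_agg <- ofv(loglik_aggregate(agg, expected_moments(m, p, dat$design, "fo")))
  expect_lt(abs(o_ind - 0.0258), 5e-5)  # exact to the 4 printed decimals
  expect_equal(o_agg, o_ind, tolerance = 1e-9)
  # proportional error
  mp <- pk_model("wang", residual_kind = "proportional")
  pp <- wang_params(proportional = TRUE)
  o_ind_p <- ofv(loglik_individual(dat, mp, pp, "fo")$loglik)
  o_agg_p <- ofv(loglik_aggregate(agg, expected_moments(mp, pp, dat$design, "fo")))
  expect_lt(abs(o_ind_p - 39.2132), 5e-5)
  expect_equal(o_agg_p, o_ind_p, tolerance = 1e-9)
})

test_that("individual FOCE with additive error reproduces the published value", {
  dat <- wang_data()
  o <- ofv(loglik_individual(dat, pk_model("wang"), wang_params(), "foce")$loglik)
  expect_lt(abs(o - (-2.0588)), 5e-5)
})

test_that("MAP estimate solves the conditional objective (grid-search oracle)", {
  m <- pk_model("wang")
  p <- wang_params()
  d <- pk_design(c(0, 1), n_subjects = 1)
  y <- c(10.3, 5.2)
  fit <- map_random_effects(y, m, p, d)
  grid <- seq(-3 * 0.2, 3 * 0.2, length.out = 10000)
  gobj <- vapply(grid, function(b) {
    f <- predict_model(m, 0.5 * exp(b), d)
    0.5 * (sum((y - f)^2 / 0.1) + 2 * log(0.1)) + 0.5 * b^2 / 0.04
  }, numeric(1))
  expect_lt(abs(fit$b - grid[which.min(gobj)]), 1e-4)
  # exact data at b = 0: MAP is zero
  f0 <- predict_model(m, 0.5, d)
  expect_equal(map_random_effects(f0, m, p, d)$b, 0, tolerance = 1e-6)
  # vanishing omega pins the MAP at the prior mode
  tiny <- pop_params(0.5, 1e-10, sigma_add2 = 0.1)
  expect_equal(map_random_effects(y, m, tiny, d)$b, 0, tolerance = 1e-5)
})

test_that("aggregate log-likelihood follows the closed form and collapses for N=1", {
  # ybar = ytilde, V = Vtilde = I: -N K / 2
  K <- 4
  agg <- aggregate_data(rep(1, K), diag(K), 7, times = 1:K)
  mom <- predicted_moments(rep(1, K), diag(K), "fo")
  expect_equal(loglik_aggregate(agg, mom), -7 * K / 2)
  # N = 1, V = 0: equals the individual-data expression exactly
  m <- pk_model("wang")
  p <- wang_params()
  d <- pk_design(c(0, 1), n_subjects = 1)
  y <- c(9.7, 6.3)
  dat <- individual_dataset(matrix(y, 1), d)
  agg1 <- aggregate_data(y, matrix(0, 2, 2), 1, times = d$times)
  mom1 <- expected_moments(m, p, d, "fo")
  expect_equal(loglik_aggregate(agg1, mom1),
               loglik_individual(dat, m, p, "fo")$loglik, tolerance = 1e-12)
})

test_that("FO aggregate equals the sum of per-subject FO log-likelihoods", {
  m <- pk_model("twocomp_oral")
  p <- case2_params()
  for (N in c(3, 25)) {
    d <- case2_design(N)
    dat <- simulate_individuals(m, p, d, seed = N)
    mom <- expected_moments(m, p, d, "fo")
    l_agg <- loglik_aggregate(aggregate_observed(dat), mom)
    l_ind <- loglik_individual(dat, m, p, "fo")$loglik
    expect_equal(l_agg, l_ind, tolerance = 1e-8)
  }
})

test_that("aggregate log-likelihood is stationary at the observed moments", {
  set.seed(17)
  K <- 3
  A <- matrix(rnorm(9), 3)
  V <- crossprod(A) + diag(0.5, 3)
  ybar <- rnorm(3)
  agg <- aggregate_data(ybar, V, 20, times = 1:3)
  base <- loglik_aggregate(agg, predicted_moments(ybar, V, "mc"))
  for (i in 1:20) {
    dy <- rnorm(3, sd = 0.02)
    dV <- matrix(rnorm(9, sd = 0.02), 3)
    dV <- (dV + t(dV)) / 2
    pert <- loglik_aggregate(agg, predicted_moments(ybar + dy, V + dV, "mc"))
    expect_lte(pert, base + 1e-12)
  }
})

test_that("log-likelihood scales linearly in the number of subjects", {
  K <- 3
  V <- diag(c(1, 2, 3))
  mom <- predicted_moments(c(1, 2, 3.5), V + 0.1, "fo")
  l1 <- loglik_aggregate(aggregate_data(c(1.1, 2, 3), V, 10, 1:3), mom)
  l2 <- loglik_aggregate(aggregate_data(c(1.1, 2, 3), V, 30, 1:3), mom)
  expect_equal(l2, 3 * l1, tolerance = 1e-12)
})

test_that("non-positive-definite predicted covariance hits the penalty contract", {
  agg <- aggregate_data(c(1, 2), diag(2), 5, 1:2)
  badV <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  val <- loglik_aggregate(agg, predicted_moments(c(1, 2), badV, "fo"))
  expect_lte(val, -1e10)
  expect_true(is.finite(val))
})

test_that("leave-one-out MC error shrinks with the sample and vanishes without IIV", {
  m <- pk_model("twocomp_oral")
  p <- case2_params()
  d <- case2_design(200)
  agg <- aggregate_observed(simulate_individuals(m, p, d, seed = 8))
  r300 <- loo_mc_se(agg, m, p, d, approximation = "mc", n_sim = 300)
  r3000 <- loo_mc_se(agg, m, p, d, approximation = "mc", n_sim = 3000)
  expect_lt(r3000$se_per_subject, r300$se_per_subject)
  # all sampled vectors identical: no Monte-Carlo variability
  p0 <- pop_params(p$beta, rep(0, 5), sigma_add2 = 0.04)
  r0 <- loo_mc_se(agg, m, p0, d, approximation = "mc", n_sim = 50)
  expect_equal(r0$se_per_subject, 0, tolerance = 1e-10)
  # the foce flavour runs and is finite
  rf <- loo_mc_se(agg, m, p, d, approximation = "foce", n_sim = 50)
  expect_true(is.finite(rf$se_per_subject))
})
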