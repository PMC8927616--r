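test_that("restricted stationary pairs match the asymmetric-substitution forms", {
  expect_equal(restricted_stationary(0.5, 0.5, "alpha0"),
               c(p1 = 0.25, p2 = 0.5))
  expect_equal(restricted_stationary(0.5, 0.5, "alpha1"),
               c(p1 = 0.75, p2 = 0.5))
  expect_equal(restricted_stationary(0, 0.8, "alpha0"), c(p1 = 0, p2 = 0))
  # each pair equals the asymmetric stationary state with the pure strategy
  # substituted for player 1 before symmetrizing the rest
  set.seed(21)
  for (i in 1:50) {
    a <- runif(1, 0.02, 0.98); g <- runif(1, 0.02, 0.98)
    expect_equal(restricted_stationary(a, g, "alpha0"),
                 stationary_probabilities(c(0, g, a, g)), tolerance = 1e-12)
    expect_equal(restricted_stationary(a, g, "alpha1"),
                 stationary_probabilities(c(1, g, a, g)), tolerance = 1e-12)
    expect_equal(restricted_stationary(a, g, "gamma0"),
                 stationary_probabilities(c(a, 0, a, g)), tolerance = 1e-12)
    expect_equal(restricted_stationary(a, g, "gamma1"),
                 stationary_probabilities(c(a, 1, a, g)), tolerance = 1e-12)
  }
  expect_error(restricted_stationary(0, 1, "alpha0"), "degenerate")
})

test_that("restricted payoffs compose the restricted states with the payoff", {
  u <- restricted_payoffs(0.5, 0.5)
  expect_equal(u$u_alpha0, 4.75)
  expect_equal(u$u_alpha1, 3.25)
  expect_equal(u$u_gamma0, 4.75)
  expect_equal(u$u_gamma1, 3.25)
  set.seed(8)
  for (i in 1:50) {
    a <- runif(1, 0.02, 0.98); g <- runif(1, 0.02, 0.98)
    u <- restricted_payoffs(a, g)
    for (w in c("alpha0", "alpha1", "gamma0", "gamma1")) {
      p <- restricted_stationary(a, g, w)
      expect_equal(u[[paste0("u_", w)]],
                   expected_payoff(p[["p1"]], p[["p2"]]), tolerance = 1e-12)
    }
  }
})

test_that("verbatim closed forms agree for the alpha pair but not the gamma pair", {
  set.seed(9)
  a <- runif(500, 0.01, 0.99); g <- runif(500, 0.01, 0.99)
  ours <- restricted_payoffs(a, g)
  printed <- restricted_payoffs_printed(a, g)
  expect_lt(max(abs(ours$u_alpha0 - printed$u_alpha0)), 1e-10)
  expect_lt(max(abs(ours$u_alpha1 - printed$u_alpha1)), 1e-10)
  # the published gamma-pair expressions carry mistranscribed leading terms;
  # the discrepancy is systematic, not rounding
  expect_gt(max(abs(ours$u_gamma0 - printed$u_gamma0)), 0.01)
  expect_gt(max(abs(ours$u_gamma1 - printed$u_gamma1)), 0.01)
})

test_that("logit response has the analytic limits and stays in (0, 1)", {
  u <- restricted_payoffs(0.37, 0.81)
  r0 <- logit_response(u, 0)
  expect_equal(r0$alpha_response, 0.5)
  expect_equal(r0$gamma_response, 0.5)
  r1 <- logit_response(list(u_alpha0 = 4.75, u_alpha1 = 3.25,
                            u_gamma0 = 0, u_gamma1 = 0), 1)
  expect_equal(r1$alpha_response, 1 / (1 + exp(1.5)), tolerance = 1e-12)
  rs <- logit_response(list(u_alpha0 = 0, u_alpha1 = 1e9,
                            u_gamma0 = 1e9, u_gamma1 = 0), 2)
  expect_equal(rs$alpha_response, 1)
  expect_equal(rs$gamma_response, 0)
})

test_that("the residual is a sum of squares, zero only at fixed points", {
  expect_equal(qre_residual(0.5, 0.5, 0), 0)
  set.seed(14)
  a <- runif(100); g <- runif(100); lam <- runif(100, 0, 20)
  r <- mapply(qre_residual, a, g, lam)
  expect_true(all(r >= 0))
  # at (0, 0) the alpha-logit saturates to defection but the gamma-payoffs
  # tie exactly (both restricted states sit at mutual defection), so the
  # gamma-response is 1/2 and the residual approaches 0.25, not 0
  u00 <- restricted_payoffs(0, 0)
  expect_equal(u00$u_gamma0, u00$u_gamma1)
  r200 <- logit_response(u00, 200)
  expect_lt(r200$alpha_response, 1e-6)
  expect_equal(r200$gamma_response, 0.5)
  expect_equal(qre_residual(0, 0, 200), 0.25, tolerance = 1e-6)
})

test_that("residual stays finite under extreme rationality", {
  x <- seq(0, 1, length.out = 21)
  grid <- expand.grid(a = x, g = x)
  vals <- qre_residual(grid$a, grid$g, 1e6)
  expect_true(all(is.finite(vals)))
})

test_that("solve_qre finds the analytic fixed point at zero rationality", {
  s <- solve_qre(0)
  expect_lt(abs(s$alpha - 0.5) + abs(s$gamma - 0.5), 1e-9)
  expect_lt(s$residual, 1e-12)
  expect_true(s$converged)
})

test_that("solve_qre matches the dense-grid global-minimum oracle", {
  for (lam in c(0.5, 3)) {
    s <- solve_qre(lam)
    o <- grid_argmin(lam, 401L)
    expect_lt(max(abs(c(s$alpha - o[["alpha"]], s$gamma - o[["gamma"]]))),
              1e-3)
  }
})

test_that("converged solutions satisfy the fixed-point equations", {
  for (lam in c(0.5, 1, 2, 5)) {
    s <- solve_qre(lam)
    expect_true(s$converged)
    r <- logit_response(restricted_payoffs(s$alpha, s$gamma), lam)
    expect_lt(abs(r$alpha_response - s$alpha), 1e-5)
    expect_lt(abs(r$gamma_response - s$gamma), 1e-5)
  }
})

test_that("warm-start tie-breaking keeps the continuation branch connected", {
  tr <- cached_trace(8, 0.01, "multistart")
  expect_equal(tr$alpha[1], 0.5, tolerance = 1e-9)
  expect_equal(tr$gamma[1], 0.5, tolerance = 1e-9)
  small <- tr[tr$lambda < 4, ]
  steps <- sqrt(diff(small$alpha)^2 + diff(small$gamma)^2)
  expect_lt(max(steps), 0.05)
  expect_true(all(tr$converged[tr$lambda < 4]))
})

test_that("local-minima census reflects the residual landscape", {
  expect_identical(as.integer(count_local_minima(0, 201L)), 1L)
  # a second, shallow but genuine basin (near alpha 0.27, gamma 0.95)
  # already exists at lambda = 2
  n2 <- count_local_minima(2, 201L)
  expect_identical(as.integer(n2), 2L)
  m2 <- attr(n2, "minima")
  expect_true(any(abs(m2[, 1] - 0.273) < 0.02 & abs(m2[, 2] - 0.953) < 0.02))
  expect_gte(as.integer(count_local_minima(6, 201L)), 2L)
  expect_error(count_local_minima(1, 51L), "101")
})

test_that("solver configuration is validated", {
  expect_error(solver_config(lambda_grid = c(2, 1)), "sorted|unsorted")
  expect_error(solver_config(lambda_grid = c(-1, 0)), ">= 0|lambda_grid")
  expect_error(solver_config(restart_grid_size = 1), "restart_grid_size")
})
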