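test_that("pseudo-observations use average ranks over n + 1", {
  expect_equal(pseudo_observations(c(1, 2, 3)), c(0.25, 0.5, 0.75))
  expect_equal(pseudo_observations(c(1, 1, 2)), c(0.375, 0.375, 0.75))
  x <- rnorm(50)
  expect_equal(pseudo_observations(x), pseudo_observations(exp(x)))
  expect_error(pseudo_observations(rep(2, 5)), "constant")
  m <- cbind(a = c(3, 1, 2), b = c(1, 2, 3))
  expect_equal(pseudo_observations(m)[, "a"], c(0.75, 0.25, 0.5))
})

test_that("asymmetry MLEs match hand evaluations", {
  # single observation u = 0.5: (0.5 log 0.5 - 0.5) / (0.5 log 0.5)
  e1 <- suppressWarnings(estimate_alpha_beta(0.5, 0.5))
  expect_equal(e1$alpha_hat, (0.5 * log(0.5) - 0.5) / (0.5 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(e1$alpha_hat, 2.442695, tolerance = 1e-6)
  u2 <- c(0.2, 0.8)
  hand <- sum((1 - u2) * log(1 - u2) - u2) / sum(u2 * log(1 - u2))
  e2 <- suppressWarnings(estimate_alpha_beta(u2, u2))
  expect_equal(e2$alpha_hat, hand, tolerance = 1e-12)
  expect_equal(e2$alpha_hat, 1.1263, tolerance = 1e-4)
  # symmetry of the two formulas
  u <- runif(20)
  e3 <- suppressWarnings(estimate_alpha_beta(u, u))
  expect_equal(e3$alpha_hat, e3$beta_hat)
  expect_error(estimate_alpha_beta(c(0, 0.5), c(0.5, 0.5)), "strictly inside")
})

test_that("admissibility bound matches hand values and is symmetric", {
  expect_equal(admissibility_bound(3, 3), 4)
  expect_equal(admissibility_bound(3, 100), 4)
  expect_gt(((100 + 1) / (100 - 1))^99, 4) # the discarded term
  expect_equal(admissibility_bound(2.2, 7.5), admissibility_bound(7.5, 2.2))
  expect_error(admissibility_bound(1, 2), "alpha > 1")
})

test_that("closed-form directional dependence matches hand evaluations", {
  expect_equal(rho_closed_form(rluf_params(0, 2, 3), "v_to_u"), 0)
  expect_equal(rho_closed_form(rluf_params(0, 2, 3), "u_to_v"), 0)
  p <- rluf_params(1, 2, 3)
  expect_equal(rho_closed_form(p, "v_to_u"), 108 / 125)
  expect_equal(rho_closed_form(p, "u_to_v"), 108 / 112)
  # monotone in |theta| for fixed alpha, beta
  th <- seq(0, 1, by = 0.2)
  r <- vapply(th, function(t) rho_closed_form(rluf_params(t, 2, 3)), 0)
  expect_true(all(diff(r) > 0))
  expect_equal(rho_closed_form(rluf_params(-0.5, 2, 3)),
               rho_closed_form(rluf_params(0.5, 2, 3)))
})

test_that("copula-regression measure is 0 at independence, 1 at comonotonicity", {
  expect_equal(rho_from_regression(copula_spec("independence")), 0,
               tolerance = 1e-8)
  # Gumbel with large theta approaches the comonotone copula M(u,v)
  near_M <- copula_spec("tawn1", tawn_params(1, 1, 200))
  expect_equal(rho_from_regression(near_M, "v_to_u"), 1, tolerance = 0.02)
  # range bound for assorted copulas
  for (sp in list(copula_spec("rluf", rluf_params(0.9, 2, 3)),
                  copula_spec("tawn1", tawn_params(0.5, 1, 30)),
                  copula_spec("bb1", bb1_params(0.5, 2)))) {
    r <- rho_from_regression(sp)
    expect_gte(r, -3); expect_lte(r, 9)
  }
})

test_that("regression measure on the RLUF family scales as theta squared", {
  # both Eq-11 and the conditional-mean measure are quadratic in theta, so
  # their ratio is a (documented) family constant in theta
  ratio <- function(th) {
    rho_from_regression(copula_spec("rluf", rluf_params(th, 2, 3)), "v_to_u") /
      rho_closed_form(rluf_params(th, 2, 3), "v_to_u")
  }
  expect_equal(ratio(0.3), ratio(0.9), tolerance = 1e-6)
  # and the quadrature agrees with the semi-analytic reduction
  # E[r(V)^2] with r(v) = 1/2 - theta g(v) / ((alpha+1)(alpha+2)),
  # g(v) = (1-v)^beta - beta v (1-v)^(beta-1), E[g] = 0
  th <- 0.7; a <- 2; b <- 3
  g2 <- stats::integrate(function(v) {
    ((1 - v)^b - b * v * (1 - v)^(b - 1))^2
  }, 0, 1, rel.tol = 1e-12)$value
  expected <- 12 * th^2 * g2 / ((a + 1) * (a + 2))^2
  got <- rho_from_regression(copula_spec("rluf", rluf_params(th, a, b)),
                             "v_to_u")
  expect_equal(got, expected, tolerance = 1e-7)
})

test_that("empirical dependence estimate is deterministic, null at independence, and monotone", {
  s0 <- sample_copula(copula_spec("independence"), 5000, seed = 3)
  r0 <- rho_empirical(s0$u, s0$v, as_pseudo = FALSE)
  expect_lt(abs(r0$rho_hat), 0.02)
  r0b <- rho_empirical(s0$u, s0$v, as_pseudo = FALSE)
  expect_identical(r0, r0b)
  # stronger association in the generator yields a larger estimate
  s_weak <- sample_copula(copula_spec("rluf", rluf_params(0.3, 2, 3)), 5000,
                          seed = 4)
  s_strong <- sample_copula(copula_spec("rluf", rluf_params(0.95, 2, 3)), 5000,
                            seed = 4)
  rw <- rho_empirical(s_weak$u, s_weak$v, as_pseudo = FALSE)$rho_hat
  rs <- rho_empirical(s_strong$u, s_strong$v, as_pseudo = FALSE)$rho_hat
  expect_gt(rs, rw)
})

test_that("regression-method empirical estimate recovers the true measure", {
  sp <- copula_spec("tawn1", tawn_params(0.5, 1, 30))
  sc <- sample_copula(sp, 5000, seed = 9)
  est <- rho_empirical(sc$u, sc$v, "v_to_u", as_pseudo = FALSE,
                       method = "regression")$rho_hat
  expect_equal(est, rho_from_regression(sp, "v_to_u"), tolerance = 0.1)
})

test_that("copula-derived Gamma prior has the exact transformed-normal law", {
  pr <- dirclust:::directional_prior(3, 3, 4)
  expect_equal(pr$shape, 0.5)
  # change-of-variables oracle: rate = 1 / (2 c (b/3)^2), c = 243/175
  expect_equal(pr$rate, 1 / (2 * (243 / 175) * (4 / 3)^2), tolerance = 1e-12)
  expect_equal(pr$rate, 0.2025, tolerance = 1e-3)
  # Monte-Carlo distribution oracle: c * theta^2 ~ Gamma(1/2, rate)
  set.seed(11)
  cc <- 3 * 9 * 9 / ((2 + 3)^2 * (1 + 2 * 3))
  draws <- cc * stats::rnorm(1e5, 0, 4 / 3)^2
  ks <- suppressWarnings(
    stats::ks.test(draws, stats::pgamma, shape = 0.5, rate = pr$rate)
  )$statistic
  expect_lt(ks, 0.01)
})

test_that("build_prior averages per-sample estimates and takes the minimal bound", {
  set.seed(21)
  u_view <- matrix(rnorm(200), 50, 4)
  v_view <- matrix(rnorm(200, 1, 2), 50, 4)
  pr <- suppressWarnings(build_prior(u_view, v_view))
  expect_s3_class(pr, "directional_prior")
  expect_equal(pr$shape, 0.5)
  U <- pseudo_observations(u_view)
  a_i <- suppressWarnings(apply(U, 1, dirclust:::alpha_mle_one))
  expect_equal(pr$alpha_hat, mean(a_i))
  V <- pseudo_observations(v_view)
  b_i <- suppressWarnings(apply(V, 1, dirclust:::alpha_mle_one))
  f <- function(a) ((a + 1) / (a - 1))^(a - 1)
  expect_equal(pr$bound, min(c(f(a_i), f(b_i))))
  expect_error(build_prior(u_view, v_view[1:10, ]), "same samples")
  # univariate views use the single-observation closed form
  pr1 <- suppressWarnings(build_prior(u_view[, 1, drop = FALSE],
                                      v_view[, 1, drop = FALSE]))
  expect_gt(pr1$rate, 0)
})
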