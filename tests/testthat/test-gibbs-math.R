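test_that("normalizing constant factorizes with no coupling and matches enumeration", {
  g2 <- small_graph2()
  em <- dirclust:::edge_index_matrix(g2)
  gam <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(compute_Z(gam, 1, g2), 6) # 2 * (1 + 1) + 2 * 1
  # rho = 0: product of per-view sums
  set.seed(31)
  gam2 <- matrix(rgamma(6, 2), 2, 3)
  g2b <- dependency_graph(c("A", "B"), rbind(c("A", "B")))
  expect_equal(compute_Z(gam2, 0, g2b), prod(rowSums(gam2)), tolerance = 1e-12)

  # M = 3 chain graph vs brute-force enumeration
  g3 <- dependency_graph(c("A", "B", "C"),
                         rbind(c("A", "B"), c("B", "C")))
  em3 <- dirclust:::edge_index_matrix(g3)
  for (rep in 1:5) {
    gam3 <- matrix(rgamma(6, 1.5), 3, 2)
    rho3 <- rgamma(2, 1)
    expect_equal(compute_Z(gam3, rho3, g3),
                 brute_Z(gam3, rho3, em3, 2), tolerance = 1e-12)
    expect_equal(dirclust:::compute_Z_cpp(gam3, rho3, em3),
                 compute_Z(gam3, rho3, g3), tolerance = 1e-14)
  }
  # and on the four-view central-dogma-like DAG
  g4 <- dependency_graph(c("GE", "ME", "miRNA", "RPPA"),
                         rbind(c("GE", "RPPA"), c("GE", "miRNA"),
                               c("miRNA", "RPPA"), c("ME", "miRNA")))
  em4 <- dirclust:::edge_index_matrix(g4)
  gam4 <- matrix(rgamma(8, 1), 4, 2)
  rho4 <- rgamma(4, 1)
  expect_equal(compute_Z(gam4, rho4, g4), brute_Z(gam4, rho4, em4, 2),
               tolerance = 1e-12)
})

test_that("gamma conditional matches the enumeration oracle", {
  set.seed(32)
  g2 <- small_graph2()
  em <- dirclust:::edge_index_matrix(g2)
  gam <- matrix(rgamma(4, 2), 2, 2)
  rho <- 0.8; xi <- 1.3
  L <- cbind(c(1L, 1L, 2L), c(2L, 1L, 2L))
  sr <- gamma_conditional(L, 1, 1, gam, rho, g2, xi, alpha_conc = 1)
  expect_equal(sr$shape, 2 + 0.5) # two objects in cluster 1 + alpha/K
  expect_equal(sr$rate, xi * brute_gamma_coef(gam, rho, em, 2, 1, 1) + 1,
               tolerance = 1e-12)
  # rho = 0 degenerate case: b = xi * prod of other views' sums + 1
  sr0 <- gamma_conditional(L, 1, 2, gam, 0, g2, xi)
  expect_equal(sr0$rate, xi * sum(gam[2, ]) + 1, tolerance = 1e-12)
  # three views, every (view, cluster) pair against enumeration
  g3 <- dependency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")))
  em3 <- dirclust:::edge_index_matrix(g3)
  gam3 <- matrix(rgamma(9, 1), 3, 3)
  rho3 <- rgamma(2, 1)
  L3 <- matrix(sample(1:3, 12, replace = TRUE), 4, 3)
  for (m in 1:3) {
    A_cpp <- dirclust:::gamma_rate_coef_cpp(gam3, rho3, em3, m)
    for (j in 1:3) {
      expect_equal(dirclust:::gamma_rate_coef(gam3, rho3, g3, m)[j],
                   brute_gamma_coef(gam3, rho3, em3, 3, m, j),
                   tolerance = 1e-12)
      expect_equal(A_cpp[j], brute_gamma_coef(gam3, rho3, em3, 3, m, j),
                   tolerance = 1e-12)
    }
  }
})

test_that("rho conditional matches the enumeration oracle", {
  set.seed(33)
  g2 <- small_graph2()
  em <- dirclust:::edge_index_matrix(g2)
  gam <- matrix(rgamma(4, 2), 2, 2)
  rho <- 0.4; xi <- 0.9
  prior <- dirclust:::directional_prior(2.5, 3.5, 2)
  L <- cbind(c(1L, 1L, 2L), c(1L, 2L, 2L))  # agreement on objects 1, 3
  sr <- rho_conditional(L, 1, gam, rho, g2, xi, prior)
  expect_equal(sr$shape, 2 + 0.5)
  expect_equal(sr$rate, xi * brute_rho_coef(gam, rho, em, 2, 1) + prior$rate,
               tolerance = 1e-12)
  # full agreement gives shape N + 1/2
  L_all <- cbind(c(1L, 2L, 1L), c(1L, 2L, 1L))
  expect_equal(rho_conditional(L_all, 1, gam, rho, g2, xi, prior)$shape, 3.5)
  # multi-edge graph, each edge against enumeration (R and C++)
  g3 <- dependency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  em3 <- dirclust:::edge_index_matrix(g3)
  gam3 <- matrix(rgamma(9, 1), 3, 3)
  rho3 <- rgamma(2, 1)
  for (e in 1:2) {
    expect_equal(dirclust:::rho_rate_coef(gam3, rho3, g3, e),
                 brute_rho_coef(gam3, rho3, em3, 3, e), tolerance = 1e-12)
    expect_equal(dirclust:::rho_rate_coef_cpp(gam3, rho3, em3, e),
                 brute_rho_coef(gam3, rho3, em3, 3, e), tolerance = 1e-12)
  }
})

test_that("auxiliary-variable draw has the Gamma(N, Z) law", {
  set.seed(34)
  draws <- replicate(1e5, sample_xi(4, 2))
  expect_true(all(draws > 0))
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(4 / 2^2 / 1e5)) # mean N/Z
  set.seed(7); a <- sample_xi(10, 3)
  set.seed(7); b <- sample_xi(10, 3)
  expect_identical(a, b)
})

test_that("collapsed marginal likelihood matches quadrature and bookkeeping", {
  base <- nig_base(mu0 = 0, kappa0 = 1, a0 = 1, b0 = 1)
  # empty component: semi-analytic quadrature of the Normal x NIG integral
  for (x in c(0, 1.3, -2.1)) {
    expect_equal(marginal_loglik(x, matrix(0, 0, 1), base),
                 log(quad_nig_predictive(x, 0, 1, 1, 1)), tolerance = 1e-8)
  }
  # permutation invariance (exchangeability)
  mem <- matrix(rnorm(12), 6, 2)
  x <- rnorm(2)
  expect_equal(marginal_loglik(x, mem, base),
               marginal_loglik(x, mem[sample(6), ], base))
  # product over independent features
  expect_equal(marginal_loglik(x, mem, base),
               marginal_loglik(x[1], mem[, 1, drop = FALSE], base) +
                 marginal_loglik(x[2], mem[, 2, drop = FALSE], base))
})

test_that("allocation conditional reduces to the standard collapsed mixture when rho = 0", {
  set.seed(35)
  g2 <- small_graph2()
  data <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2))
  gam <- matrix(rgamma(4, 2), 2, 2)
  L <- cbind(c(1L, 2L, 1L), c(2L, 2L, 1L))
  base <- nig_base()
  pr <- allocation_probs(data, i = 2, m = 1, L, gam, 0, g2, K = 2, base)
  direct <- vapply(1:2, function(c) {
    members <- data[[1]][L[, 1] == c & seq_len(3) != 2, , drop = FALSE]
    gam[1, c] * exp(marginal_loglik(data[[1]][2, ], members, base))
  }, 0)
  expect_equal(pr, direct / sum(direct), tolerance = 1e-12)
})

test_that("allocation conditional matches brute-force enumeration of the joint", {
  set.seed(36)
  g2 <- small_graph2()
  em <- dirclust:::edge_index_matrix(g2)
  data <- list(matrix(rnorm(3), 3, 1), matrix(rnorm(3), 3, 1))
  gam <- matrix(rgamma(4, 2), 2, 2)
  rho <- 1.7
  base <- nig_base()
  L <- cbind(c(1L, 2L, 1L), c(2L, 2L, 1L))
  for (i in 1:3) {
    for (m in 1:2) {
      pr <- allocation_probs(data, i, m, L, gam, rho, g2, K = 2, base)
      # enumerate p(L_mi = c | everything else) from the full joint
      w <- vapply(1:2, function(c) {
        Lc <- L; Lc[i, m] <- c
        brute_alloc_joint(Lc, gam, rho, em) *
          exp(brute_data_loglik(data[[m]], Lc[, m], base))
      }, 0)
      expect_equal(pr, w / sum(w), tolerance = 1e-10)
    }
  }
  # dominant coupling forces agreement with the neighbour's label
  pr_big <- allocation_probs(data, 1, 2, L, gam, 1e9, g2, K = 2, base)
  expect_gt(pr_big[L[1, 1]], 0.999)
})

test_that("chain caches of Z agree with recomputation from retained states", {
  sim <- generate_views(40, seed = 51)
  g <- dependency_graph(c("U", "V"), rbind(c("V", "U")), terminal = "U")
  fit <- dirclust(sim$views, g, K = 5, iterations = 60, burn_in = 20,
                  seed = 3)
  for (t in c(1, 10, 40)) {
    gam_t <- matrix(fit$gamma_chain[t, , ], nrow = fit$M)
    expect_equal(fit$Z_chain[t],
                 compute_Z(gam_t, fit$rho_chain[t, ], g), tolerance = 1e-10)
  }
})
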