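# Distributional checks of the C++ sweep against enumerable targets.

test_that("allocation-only sweeps target the coupled allocation prior", {
  # M = 2, K = 2, N = 3, fixed gamma/rho/xi, no data: the stationary law of
  # the allocation scan is the coupled prior, enumerable over 2^6 states
  g2 <- small_graph2()
  em <- dirclust:::edge_index_matrix(g2)
  gam <- matrix(c(1.2, 0.7, 0.9, 1.4), 2, 2)
  rho <- 1.5
  N <- 3; K <- 2
  # enumerate the target
  states <- as.matrix(expand.grid(rep(list(1:2), 6)))
  target <- apply(states, 1, function(s) {
    L <- matrix(as.integer(s), N, 2)
    brute_alloc_joint(L, gam, rho, em)
  })
  target <- target / sum(target)
  data0 <- list(matrix(0, N, 0), matrix(0, N, 0)) # no data: likelihood = 1
  set.seed(41)
  res <- dirclust:::gibbs_run_cpp(
    data0, list(numeric(0), numeric(0)), em, prior_rate = 1, K = K,
    alpha_conc = 1, kappa0 = 0.01, a0 = 1, b0 = 1,
    iterations = 100000L, burn_in = 1000L, thinning = 10L,
    L_init = matrix(1L, N, 2), gamma_init = gam, rho_init = rho,
    xi_init = 1, update_xi = FALSE, update_gamma = FALSE,
    update_rho = FALSE, verbose = FALSE)
  Lc <- res$L_chain
  n_keep <- dim(Lc)[1]
  code <- integer(n_keep)
  for (m in 1:2) {
    for (i in 1:3) {
      code <- code * 2L + (Lc[, i, m] - 1L)
    }
  }
  # map enumeration to the same coding
  code_target <- apply(states, 1, function(s) {
    L <- matrix(as.integer(s), N, 2)
    cd <- 0L
    for (m in 1:2) for (i in 1:3) cd <- cd * 2L + (L[i, m] - 1L)
    cd
  })
  obs <- tabulate(code + 1L, nbins = 64)
  exp_counts <- numeric(64)
  exp_counts[code_target + 1L] <- target * n_keep
  chisq <- sum((obs - exp_counts)^2 / exp_counts)
  pval <- stats::pchisq(chisq, df = 63, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("single uncoupled view reproduces the Dirichlet-multinomial mixture law", {
  # M = 1: marginalizing gamma and xi, the allocation law is the symmetric
  # Dirichlet-multinomial EPPF times the collapsed likelihood; compare the
  # full sampler's state distribution with enumeration (TV < 0.05)
  set.seed(42)
  x <- matrix(c(-0.3, 0.1, 2.5), 3, 1)
  K <- 2; N <- 3; alpha <- 1
  base <- nig_base()
  g1 <- dependency_graph("A")
  em <- dirclust:::edge_index_matrix(g1)
  states <- as.matrix(expand.grid(rep(list(1:2), N)))
  target <- apply(states, 1, function(s) {
    counts <- tabulate(s, K)
    prior <- prod(gamma(alpha / K + counts) / gamma(alpha / K))
    prior * exp(brute_data_loglik(x, s, base))
  })
  target <- target / sum(target)
  res <- dirclust:::gibbs_run_cpp(
    list(x), list(0), em, prior_rate = numeric(0), K = K,
    alpha_conc = alpha, kappa0 = base$kappa0, a0 = base$a0, b0 = base$b0,
    iterations = 60000L, burn_in = 2000L, thinning = 5L,
    L_init = matrix(1L, N, 1), gamma_init = matrix(1, 1, K),
    rho_init = numeric(0), xi_init = 1,
    update_xi = TRUE, update_gamma = TRUE, update_rho = FALSE,
    verbose = FALSE)
  Lc <- matrix(res$L_chain[, , 1], nrow = dim(res$L_chain)[1])
  code <- (Lc[, 1] - 1) * 4 + (Lc[, 2] - 1) * 2 + (Lc[, 3] - 1) + 1
  emp <- tabulate(code, 8) / length(code)
  code_target <- (states[, 1] - 1) * 4 + (states[, 2] - 1) * 2 + states[, 3]
  tv <- 0.5 * sum(abs(emp[code_target] - target))
  expect_lt(tv, 0.05)
})

test_that("the full chain is reproducible from its seed", {
  sim <- generate_views(30, seed = 8)
  g <- dependency_graph(c("U", "V"), rbind(c("V", "U")), terminal = "U")
  f1 <- dirclust(sim$views, g, K = 5, iterations = 80, seed = 99)
  f2 <- dirclust(sim$views, g, K = 5, iterations = 80, seed = 99)
  expect_identical(f1$L_chain, f2$L_chain)
  expect_identical(f1$rho_chain, f2$rho_chain)
  expect_identical(f1$xi_chain, f2$xi_chain)
})

test_that("well-separated two-cluster data is recovered essentially always", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(c(rnorm(25, -5), rnorm(25, 5)), ncol = 1)
    fit <- dirclust(list(A = x), dependency_graph("A"), K = 25,
                    iterations = 400, seed = s)
    acc <- clustering_accuracy(rep(1:2, each = 25), consensus_labels(fit))
    hits <- hits + (acc == 1)
  }
  expect_gte(hits, 9)
})

test_that("uncoupled views cluster independently", {
  # independent memberships in the two views; with no edges the consensus
  # partitions of the views should agree only at the chance level
  set.seed(44)
  n <- 120
  zu <- sample(1:2, n, TRUE); zv <- sample(1:2, n, TRUE)
  views <- list(U = matrix(rnorm(n, c(-3, 3)[zu]), ncol = 1),
                V = matrix(rnorm(n, c(-3, 3)[zv]), ncol = 1))
  g <- dependency_graph(c("U", "V"), NULL, terminal = "U")
  fit <- dirclust(views, g, K = 10, iterations = 600, seed = 4)
  lu <- consensus_labels(fit, "U"); lv <- consensus_labels(fit, "V")
  expect_gt(clustering_accuracy(zu, lu), 0.95)
  expect_gt(clustering_accuracy(zv, lv), 0.95)
  # Rand index between the two views' partitions stays near the 0.5
  # chance level for independent balanced 2-cluster partitions
  expect_lt(abs(rand_index(lu, lv) - 0.5), 0.12)
})

test_that("occupied-cluster count stays within K and finds the true count", {
  sim <- simulation_scenario("no_direction", n = 200, seed = 13)
  fit <- dirclust(sim$views, sim$graph, iterations = 800, seed = 13)
  occ <- occupied_clusters(fit)
  expect_true(all(occ$counts <= fit$K))
  expect_equal(occ$mode, 2L)
})

test_that("misaligned views are rejected with an informative error", {
  sim <- generate_views(30, seed = 2)
  g <- dependency_graph(c("U", "V"), rbind(c("V", "U")), terminal = "U")
  bad <- sim$views
  bad$V <- bad$V[1:20, , drop = FALSE]
  expect_error(dirclust(bad, g, K = 4, iterations = 50, seed = 1),
               "aligned")
  expect_error(dirclust(sim$views, g, K = 4, iterations = 50,
                        burn_in = 100, seed = 1), "burn_in")
})
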