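# Exact evaluation of the allocation-prior normalizing constant and the
# Gamma-rate coefficients of the sampler's conditionals.
#
# The joint allocation prior couples views only through pairwise equality
# indicators along the dependency graph, so the K^M sum
#   Z = sum_{j_1..j_M} prod_m gamma_{m j_m} prod_{(m,k) in E} (1 + rho 1{j_m = j_k})
# expands exactly over edge subsets: each product factor is (1 + rho delta),
# hence Z = sum_{S subseteq E} prod_{e in S} rho_e * prod_{components c of S}
# sum_k prod_{m in c} gamma_{m k}. Cost O(2^E (K + M)) independent of K^M.

# connected components of views under a set of edge rows (E' x 2 indices)
view_components <- function(M, edge_rows) {
  parent <- seq_len(M)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (NROW(edge_rows)) {
    for (r in seq_len(nrow(edge_rows))) {
      a <- find(edge_rows[r, 1]); b <- find(edge_rows[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(M), find, integer(1))
}

# sum_k prod_{m in members} gamma[m, k]
component_sum <- function(gamma, members) {
  if (length(members) == 1) return(sum(gamma[members, ]))
  sum(apply(gamma[members, , drop = FALSE], 2, prod))
}

check_edge_budget <- function(E) {
  if (E > 20) {
    stop("dependency graph has ", E, " edges; the exact edge-subset ",
         "expansion enumerates 2^E terms. Reduce the graph or prune ",
         "redundant edges.")
  }
}

#' Normalizing constant of the coupled allocation prior
#'
#' Exact value of
#' \deqn{Z = \sum_{j_1, \dots, j_M} \prod_m \gamma_{m j_m}
#'   \prod_{(m,k) \in E} (1 + \rho_{m \to k} 1\{j_m = j_k\}),}
#' computed by an inclusion expansion over edge subsets rather than by
#' enumerating the \eqn{K^M} index combinations.
#'
#' @param gamma `M x K` matrix of positive view/cluster weights, rows in
#'   the order of `graph$nodes`.
#' @param rho nonnegative dependence strengths, one per row of
#'   `graph$edges`.
#' @param graph a [dependency_graph()].
#' @return positive scalar.
#' @export
compute_Z <- function(gamma, rho, graph) {
  gamma <- as.matrix(gamma)
  em <- edge_index_matrix(graph)
  E <- nrow(em)
  check_edge_budget(E)
  stopifnot(length(rho) == E, nrow(gamma) == length(graph$nodes))
  M <- nrow(gamma)
  total <- 0
  for (S in 0:(2^E - 1)) {
    sel <- which(bitwAnd(S, bitwShiftL(1L, seq_len(E) - 1L)) != 0L)
    comp <- view_components(M, em[sel, , drop = FALSE])
    term <- prod(rho[sel])
    for (r in unique(comp)) {
      term <- term * component_sum(gamma, which(comp == r))
    }
    total <- total + term
  }
  total
}

# d Z / d gamma_{m j} for all j at once (K-vector); this is the Eq-25-style
# sum over all other views' cluster combinations with view m's index fixed
gamma_rate_coef <- function(gamma, rho, graph, m) {
  gamma <- as.matrix(gamma)
  em <- edge_index_matrix(graph)
  E <- nrow(em)
  check_edge_budget(E)
  M <- nrow(gamma); K <- ncol(gamma)
  A <- numeric(K)
  for (S in 0:(2^E - 1)) {
    sel <- which(bitwAnd(S, bitwShiftL(1L, seq_len(E) - 1L)) != 0L)
    comp <- view_components(M, em[sel, , drop = FALSE])
    others <- prod(rho[sel])
    for (r in setdiff(unique(comp), comp[m])) {
      others <- others * component_sum(gamma, which(comp == r))
    }
    mates <- setdiff(which(comp == comp[m]), m)
    vec <- if (length(mates)) {
      apply(gamma[mates, , drop = FALSE], 2, prod)
    } else {
      rep(1, K)
    }
    A <- A + others * vec
  }
  A
}

# coefficient of rho_e in Z (Z is linear in each rho): the Eq-28-style sum
# with the (m, p) equality enforced and the (m, p) factor removed
rho_rate_coef <- function(gamma, rho, graph, edge_id) {
  gamma <- as.matrix(gamma)
  em <- edge_index_matrix(graph)
  E <- nrow(em)
  check_edge_budget(E)
  stopifnot(edge_id >= 1, edge_id <= E)
  M <- nrow(gamma)
  rest <- setdiff(seq_len(E), edge_id)
  total <- 0
  for (S in 0:(2^length(rest) - 1)) {
    sel <- rest[bitwAnd(S, bitwShiftL(1L, seq_along(rest) - 1L)) != 0L]
    comp <- view_components(M, em[c(sel, edge_id), , drop = FALSE])
    term <- prod(rho[sel])
    for (r in unique(comp)) {
      term <- term * component_sum(gamma, which(comp == r))
    }
    total <- total + term
  }
  total
}

#' Draw the auxiliary variable of the coupled mixture
#'
#' The latent variable that linearizes the \eqn{Z^{-N}} normalization has
#' full conditional \eqn{\xi \mid - \sim \mathrm{Gamma}(N, Z)} (shape,
#' rate).
#'
#' @param n_samples number of objects `N`.
#' @param Z current normalizing constant, from [compute_Z()].
#' @return one positive draw.
#' @export
sample_xi <- function(n_samples, Z) {
  stopifnot(Z > 0, n_samples >= 1)
  stats::rgamma(1, shape = n_samples, rate = Z)
}

#' Full conditional of a view/cluster weight
#'
#' \eqn{\gamma_{mj} \mid - \sim \mathrm{Gamma}(a_\gamma, b_\gamma)} with
#' shape \eqn{a_\gamma = \sum_i 1\{L_{mi} = j\} + \alpha_m/K} and rate
#' \eqn{b_\gamma = \xi \,\partial Z/\partial \gamma_{mj} + 1}.
#'
#' @param L `N x M` integer allocation matrix (clusters `1..K`).
#' @param m view index; `j` cluster index.
#' @param j cluster index.
#' @param gamma,rho,graph current weights, strengths, and the graph.
#' @param xi current auxiliary variable.
#' @param alpha_conc Dirichlet-type concentration \eqn{\alpha_m}
#'   (default 1).
#' @return tibble with columns `shape` and `rate`.
#' @export
gamma_conditional <- function(L, m, j, gamma, rho, graph, xi, alpha_conc = 1) {
  K <- ncol(as.matrix(gamma))
  A <- gamma_rate_coef(gamma, rho, graph, m)
  tibble::tibble(
    shape = sum(L[, m] == j) + alpha_conc / K,
    rate = xi * A[j] + 1
  )
}

#' @rdname gamma_conditional
#' @export
sample_gamma <- function(L, m, j, gamma, rho, graph, xi, alpha_conc = 1) {
  sr <- gamma_conditional(L, m, j, gamma, rho, graph, xi, alpha_conc)
  stats::rgamma(1, shape = sr$shape, rate = sr$rate)
}

#' Full conditional of a directional dependence strength
#'
#' \eqn{\rho_{m \to p} \mid - \sim \mathrm{Gamma}(a_\rho, b_\rho)} with
#' shape \eqn{a_\rho = \sum_i 1\{L_{mi} = L_{pi}\} + 1/2} and rate
#' \eqn{b_\rho = \xi\, \partial Z/\partial \rho_{m \to p} +
#' \mathrm{rate}_0}, where \eqn{\mathrm{rate}_0} is the copula-derived
#' prior rate (see [build_prior()]).
#'
#' @inheritParams gamma_conditional
#' @param edge_id row index into `graph$edges`.
#' @param prior a `directional_prior` for this edge.
#' @return tibble with columns `shape` and `rate`.
#' @export
rho_conditional <- function(L, edge_id, gamma, rho, graph, xi, prior) {
  stopifnot(inherits(prior, "directional_prior"))
  em <- edge_index_matrix(graph)
  m <- em[edge_id, 1]; p <- em[edge_id, 2]
  D <- rho_rate_coef(gamma, rho, graph, edge_id)
  tibble::tibble(
    shape = sum(L[, m] == L[, p]) + prior$shape,
    rate = xi * D + prior$rate
  )
}

#' @rdname rho_conditional
#' @export
sample_rho <- function(L, edge_id, gamma, rho, graph, xi, prior) {
  sr <- rho_conditional(L, edge_id, gamma, rho, graph, xi, prior)
  stats::rgamma(1, shape = sr$shape, rate = sr$rate)
}

#' Normal--Inverse-Gamma base measure
#'
#' Conjugate per-feature base measure for the collapsed allocation update:
#' each feature is modelled Normal with NIG prior
#' \eqn{(\mu_0, \kappa_0, a_0, b_0)}, so the posterior predictive of a new
#' observation given a component's members is Student-t, feature-wise
#' independent.
#'
#' @param mu0 prior mean (scalar, recycled over features).
#' @param kappa0 prior precision scaling (default 0.01, weakly
#'   informative).
#' @param a0,b0 Inverse-Gamma shape/scale (defaults 1, 1).
#' @return list of class `nig_base`.
#' @export
nig_base <- function(mu0 = 0, kappa0 = 0.01, a0 = 1, b0 = 1) {
  stopifnot(kappa0 > 0, a0 > 0, b0 > 0)
  structure(list(mu0 = mu0, kappa0 = kappa0, a0 = a0, b0 = b0),
            class = "nig_base")
}

#' Collapsed marginal log-likelihood of an observation in a component
#'
#' Log posterior-predictive density of `x` given the component's current
#' members under the NIG base measure: the integral
#' \eqn{\int f(x \mid \theta)\, g^{(0)}(\theta \mid \text{members})\,
#' d\theta}, available in closed form as a product of Student-t densities
#' over features.
#'
#' @param x numeric vector (one observation, length = number of features).
#' @param members matrix of the component's other members (rows =
#'   observations); may have zero rows for an empty component.
#' @param base a [nig_base()].
#' @return log density (scalar).
#' @export
marginal_loglik <- function(x, members, base = nig_base()) {
  stopifnot(inherits(base, "nig_base"))
  members <- matrix(as.numeric(members), ncol = length(x))
  n <- nrow(members)
  s <- if (n) colSums(members) else numeric(length(x))
  q <- if (n) colSums(members^2) else numeric(length(x))
  nig_predictive_logpdf(x, n, s, q, base)
}

# vectorized over features given sufficient statistics (n, sum, sum of squares)
nig_predictive_logpdf <- function(x, n, s, q, base) {
  mu0 <- rep_len(base$mu0, length(x))
  kn <- base$kappa0 + n
  an <- base$a0 + n / 2
  xbar <- if (n > 0) s / n else numeric(length(x))
  ss <- pmax(q - n * xbar^2, 0)
  bn <- base$b0 + 0.5 * ss +
    if (n > 0) base$kappa0 * n * (xbar - mu0)^2 / (2 * kn) else 0
  mun <- (base$kappa0 * mu0 + s) / kn
  nu <- 2 * an
  scale2 <- bn * (kn + 1) / (an * kn)
  sum(stats::dt((x - mun) / sqrt(scale2), df = nu, log = TRUE) -
        0.5 * log(scale2))
}

#' Full-conditional allocation distribution of one object in one view
#'
#' The collapsed conditional \eqn{p(L_{mi} = c \mid -)} proportional to
#' \eqn{\gamma_{mc}} times the incoming- and outgoing-edge factors
#' \eqn{(1 + \rho\,1\{\cdot = c\})} times the collapsed predictive of
#' \eqn{x_{mi}} in component `c` (excluding object `i`). Normalized to sum
#' to one via log-sum-exp.
#'
#' @param data list of `N x D_m` view matrices, in `graph$nodes` order.
#' @param i object index; `m` view index.
#' @param m view index.
#' @param L `N x M` allocation matrix (the value `L[i, m]` is ignored).
#' @param gamma,rho,graph current state and graph.
#' @param K number of mixture components.
#' @param base a [nig_base()].
#' @return probability vector of length `K`.
#' @export
allocation_probs <- function(data, i, m, L, gamma, rho, graph, K,
                             base = nig_base()) {
  em <- edge_index_matrix(graph)
  x <- as.numeric(data[[m]][i, , drop = TRUE])
  logw <- numeric(K)
  for (c in seq_len(K)) {
    members <- data[[m]][L[, m] == c & seq_len(nrow(L)) != i, , drop = FALSE]
    lw <- log(gamma[m, c]) + marginal_loglik(x, members, base)
    if (nrow(em)) {
      for (e in seq_len(nrow(em))) {
        if (em[e, 2] == m) {           # incoming k -> m
          lw <- lw + log1p(rho[e] * (L[i, em[e, 1]] == c))
        } else if (em[e, 1] == m) {    # outgoing m -> k
          lw <- lw + log1p(rho[e] * (c == L[i, em[e, 2]]))
        }
      }
    }
    logw[c] <- lw
  }
  if (all(!is.finite(logw))) {
    stop("all-zero unnormalized allocation vector; log-sum-exp underflow.")
  }
  w <- exp(logw - max(logw))
  w / sum(w)
}
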