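#' Rank-based pseudo-observations
#'
#' Probability-integral transform by ranks, \eqn{r_i / (n + 1)}, mapping a
#' numeric vector (or each column of a matrix) strictly into \eqn{(0, 1)}.
#' Ties receive the average rank. Invariant to monotone transforms of the
#' input, which is what makes the copula estimates margin-free.
#'
#' @param x numeric vector or matrix (columns transformed independently).
#' @return object of the same shape with entries in \eqn{(0, 1)}.
#' @export
#' @examples
#' pseudo_observations(c(1, 2, 3))
pseudo_observations <- function(x) {
  if (is.matrix(x)) {
    return(apply(x, 2, pseudo_observations))
  }
  if (length(x) < 2) stop("need at least 2 observations.")
  if (max(x) == min(x)) stop("constant vector: ranks are undefined up to ties.")
  rank(x, ties.method = "average") / (length(x) + 1)
}

# Eq-8-style moment/MLE estimator of one RLUF asymmetry parameter from
# values in (0,1); works for a single observation as well.
alpha_mle_one <- function(u, clip = TRUE) {
  num <- sum((1 - u) * log(1 - u) - u)
  den <- sum(u * log(1 - u))
  if (den == 0) stop("degenerate pseudo-observations: zero denominator in MLE.")
  est <- num / den
  if (clip && est <= 1) {
    warning("asymmetry MLE fell at or below 1; clipped to 1 + 1e-6.")
    est <- 1 + 1e-6
  }
  est
}

#' Maximum-likelihood asymmetry parameters of the RLUF copula
#'
#' Closed-form estimators
#' \deqn{\hat\alpha = \frac{\sum_i (1-u_i)\log(1-u_i) - u_i}{\sum_i u_i \log(1-u_i)}}
#' and analogously \eqn{\hat\beta} from `v`. Estimates at or below the
#' admissible limit 1 are clipped to `1 + 1e-6` with a warning.
#'
#' @param u,v pseudo-observations strictly inside \eqn{(0, 1)}, equal length.
#' @return tibble with columns `alpha_hat`, `beta_hat`.
#' @export
#' @examples
#' estimate_alpha_beta(c(0.2, 0.8), c(0.3, 0.6))
estimate_alpha_beta <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 1)
  if (any(u <= 0 | u >= 1) || any(v <= 0 | v >= 1)) {
    stop("pseudo-observations must lie strictly inside (0, 1).")
  }
  tibble::tibble(
    alpha_hat = alpha_mle_one(u),
    beta_hat = alpha_mle_one(v)
  )
}

#' Admissibility bound for the RLUF association parameter
#'
#' Largest \eqn{|\vartheta|} keeping the RLUF function a valid copula:
#' \deqn{b(\alpha,\beta) = \min\left\{
#'   \left(\tfrac{\alpha+1}{\alpha-1}\right)^{\alpha-1},
#'   \left(\tfrac{\beta+1}{\beta-1}\right)^{\beta-1}\right\}.}
#'
#' @param alpha,beta asymmetry parameters, both \eqn{> 1} (vectorized).
#' @return the bound, a positive number.
#' @export
#' @examples
#' admissibility_bound(3, 3) # == 4
admissibility_bound <- function(alpha, beta) {
  if (any(alpha <= 1) || any(beta <= 1)) {
    stop("admissibility bound requires alpha > 1 and beta > 1.")
  }
  pmin(((alpha + 1) / (alpha - 1))^(alpha - 1),
       ((beta + 1) / (beta - 1))^(beta - 1))
}

#' Closed-form directional dependence of the RLUF copula
#'
#' \deqn{\rho_{v \to u} = \frac{3\vartheta^2\alpha^2\beta^2}{(2+\beta)^2(1+2\alpha)},
#' \qquad
#' \rho_{u \to v} = \frac{3\vartheta^2\alpha^2\beta^2}{(2+\alpha)^2(1+2\beta)}.}
#' Nonnegative; zero iff \eqn{\vartheta = 0}.
#'
#' @param p an [rluf_params()] object.
#' @param direction `"v_to_u"` (how strongly V determines U) or `"u_to_v"`.
#' @return nonnegative scalar.
#' @export
#' @examples
#' rho_closed_form(rluf_params(1, 2, 3), "v_to_u") # 108/125
rho_closed_form <- function(p, direction = c("v_to_u", "u_to_v")) {
  stopifnot(inherits(p, "rluf_params"))
  direction <- match.arg(direction)
  th <- p$theta_assoc; a <- p$alpha; b <- p$beta
  if (direction == "v_to_u") {
    3 * th^2 * a^2 * b^2 / ((2 + b)^2 * (1 + 2 * a))
  } else {
    3 * th^2 * a^2 * b^2 / ((2 + a)^2 * (1 + 2 * b))
  }
}

#' Directional dependence by copula regression (numerical)
#'
#' Computes \eqn{\rho = 12\,E[r(\cdot)^2] - 3} by Gauss-Legendre quadrature,
#' where `r` is the copula-regression (conditional-mean) function. The fixed
#' conditioning convention of this package is
#' \deqn{r(v) = E[U \mid V = v] = 1 - \int_0^1 C_{U|V}(u \mid v)\, du}
#' for direction `"v_to_u"` (and the mirror image for `"u_to_v"`), under
#' which the independence copula yields exactly 0 and the comonotone copula
#' exactly 1. All numerical uses of the measure in this package share this
#' convention.
#'
#' @param spec a [copula_spec()] (or an [rluf_params()] object, promoted to
#'   an RLUF `copula_spec`).
#' @param direction `"v_to_u"` or `"u_to_v"`.
#' @param n_grid number of quadrature nodes per axis.
#' @return scalar in \eqn{[-3, 9]} (and in \eqn{[0, 1]} for the families
#'   implemented here).
#' @export
rho_from_regression <- function(spec, direction = c("v_to_u", "u_to_v"),
                                n_grid = 64) {
  direction <- match.arg(direction)
  if (inherits(spec, "rluf_params")) {
    spec <- copula_spec("rluf", spec)
  }
  stopifnot(inherits(spec, "copula_spec"))
  gl <- gauss_legendre_01(n_grid)
  cond <- if (direction == "v_to_u") copula_conditional_v else {
    function(u, v, s) copula_conditional_u(v, u, s)
  }
  # r(v) = 1 - int_0^1 C_{.|.}(u | v) du at each outer node v
  r <- vapply(gl$nodes, function(vv) {
    f <- cond(gl$nodes, rep(vv, n_grid), spec)
    if (any(!is.finite(f))) {
      stop("quadrature failure: non-finite conditional copula values at v = ", vv)
    }
    1 - sum(gl$weights * f)
  }, numeric(1))
  12 * sum(gl$weights * r^2) - 3
}

# Gauss-Legendre nodes/weights on (0, 1)
gauss_legendre_01 <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix for P_n
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- (e$values + 1) / 2
  weights <- 2 * e$vectors[1, ]^2 / 2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

#' Plug-in directional-dependence estimate from a paired sample
#'
#' Deterministic plug-in for the closed-form measure: estimate
#' \eqn{\hat\alpha, \hat\beta} by [estimate_alpha_beta()], estimate the
#' association \eqn{\hat\vartheta} by least-squares moment matching of the
#' empirical copula against the RLUF form on a grid, clip
#' \eqn{\hat\vartheta} to the admissibility bound, and evaluate
#' [rho_closed_form()].
#'
#' @param u,v paired values; transformed to pseudo-observations internally
#'   unless already strictly inside \eqn{(0, 1)} with `as_pseudo = FALSE`.
#' @param direction `"v_to_u"` or `"u_to_v"`.
#' @param as_pseudo if `TRUE` (default) apply [pseudo_observations()] first.
#' @param method `"closed_form"` (default): the RLUF plug-in described
#'   above. `"regression"`: nonparametric plug-in of the defining measure,
#'   \eqn{12 E[\hat r^2] - 3} with \eqn{\hat r} the binned conditional-mean
#'   estimate of the downstream margin given the upstream one; unlike the
#'   closed form (whose asymmetry estimates depend on each margin alone,
#'   hence are direction-blind on uniform margins) this uses the joint law
#'   and can discriminate direction.
#' @param grid_n grid resolution per axis for the moment match.
#' @return tibble with `rho_hat`, `theta_hat`, `alpha_hat`, `beta_hat`,
#'   `bound` (the last four are `NA` for `method = "regression"`).
#' @export
rho_empirical <- function(u, v, direction = c("v_to_u", "u_to_v"),
                          as_pseudo = TRUE,
                          method = c("closed_form", "regression"),
                          grid_n = 20) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  stopifnot(length(u) == length(v), length(u) >= 10)
  if (as_pseudo) {
    u <- pseudo_observations(u)
    v <- pseudo_observations(v)
  }
  if (method == "regression") {
    if (direction == "u_to_v") { tmp <- u; u <- v; v <- tmp }
    # r(v) = E[U | V = v] estimated by equal-width bins of the upstream margin
    B <- max(10L, floor(sqrt(length(u)) / 2))
    bin <- pmin(pmax(ceiling(v * B), 1L), B)
    r_b <- tapply(u, bin, mean)
    w_b <- tabulate(bin, B)[as.integer(names(r_b))] / length(u)
    return(tibble::tibble(
      rho_hat = 12 * sum(w_b * r_b^2) - 3,
      theta_hat = NA_real_, alpha_hat = NA_real_, beta_hat = NA_real_,
      bound = NA_real_
    ))
  }
  est <- suppressWarnings(estimate_alpha_beta(u, v))
  a <- est$alpha_hat; b <- est$beta_hat
  bnd <- admissibility_bound(a, b)
  gr <- seq(1 / (grid_n + 1), grid_n / (grid_n + 1), length.out = grid_n)
  gu <- rep(gr, times = grid_n)
  gv <- rep(gr, each = grid_n)
  C_emp <- vapply(seq_along(gu), function(j) mean(u <= gu[j] & v <= gv[j]),
                  numeric(1))
  basis <- gu * gv * (1 - gu)^a * (1 - gv)^b
  theta_hat <- sum(basis * (C_emp - gu * gv)) / sum(basis^2)
  theta_hat <- max(min(theta_hat, bnd), -bnd)
  p <- rluf_params(theta_hat, a, b)
  tibble::tibble(
    rho_hat = rho_closed_form(p, direction),
    theta_hat = theta_hat,
    alpha_hat = a,
    beta_hat = b,
    bound = bnd
  )
}

#' Copula-derived Gamma prior on a directional dependence strength
#'
#' For an ordered pair of views (upstream `u_view`, downstream `v_view`),
#' builds the prior on the coupling strength \eqn{\rho_{u \to v}} used by
#' the Gibbs sampler:
#' per-sample RLUF asymmetry estimates \eqn{\hat\alpha_{uv,i},
#' \hat\beta_{uv,i}} are computed from each sample's pseudo-observations
#' and averaged to \eqn{\hat\alpha_{uv}, \hat\beta_{uv}}; the association
#' bound \eqn{b_{uv}} is the minimum over samples of the per-sample
#' admissibility bounds; and with \eqn{\vartheta \sim N(0, (b_{uv}/3)^2)}
#' (so that \eqn{P(|\vartheta| \le b_{uv}) = 0.997}) the induced law of
#' \eqn{\rho = c\,\vartheta^2}, \eqn{c = 3\hat\alpha^2\hat\beta^2 /
#' ((2+\hat\alpha)^2(1+2\hat\beta))}, is exactly
#' \deqn{\rho \sim \mathrm{Gamma}\!\left(\tfrac12,\;
#'   \mathrm{rate} = \frac{1}{2\,c\,(b_{uv}/3)^2}\right).}
#'
#' @param u_view,v_view numeric matrices (samples x features) with equal
#'   row counts; data frames are accepted. Univariate views (one feature)
#'   are allowed: the per-sample estimate then uses the single-observation
#'   closed form.
#' @return An object of class `directional_prior`: a list with
#'   `alpha_hat`, `beta_hat`, `bound`, `shape` (always 1/2), `rate`.
#' @export
build_prior <- function(u_view, v_view) {
  u_view <- as.matrix(u_view); v_view <- as.matrix(v_view)
  if (nrow(u_view) != nrow(v_view)) {
    stop("views must share the same samples (equal row counts).")
  }
  if (nrow(u_view) < 2) stop("need at least 2 samples.")
  U <- pseudo_observations(u_view)
  V <- pseudo_observations(v_view)
  a_i <- suppressWarnings(apply(U, 1, alpha_mle_one))
  b_i <- suppressWarnings(apply(V, 1, alpha_mle_one))
  alpha_hat <- mean(a_i)
  beta_hat <- mean(b_i)
  bound <- min(pmin(((a_i + 1) / (a_i - 1))^(a_i - 1),
                    ((b_i + 1) / (b_i - 1))^(b_i - 1)))
  cc <- 3 * alpha_hat^2 * beta_hat^2 /
    ((2 + alpha_hat)^2 * (1 + 2 * beta_hat))
  rate <- 1 / (2 * cc * (bound / 3)^2)
  structure(
    list(alpha_hat = alpha_hat, beta_hat = beta_hat, bound = bound,
         shape = 0.5, rate = rate),
    class = "directional_prior"
  )
}

# prior object from already-known averaged parameters (used in tests and by
# power users who estimated alpha, beta, b elsewhere)
directional_prior <- function(alpha_hat, beta_hat, bound) {
  stopifnot(alpha_hat > 1, beta_hat > 1, bound > 0)
  cc <- 3 * alpha_hat^2 * beta_hat^2 /
    ((2 + alpha_hat)^2 * (1 + 2 * beta_hat))
  structure(
    list(alpha_hat = alpha_hat, beta_hat = beta_hat, bound = bound,
         shape = 0.5, rate = 1 / (2 * cc * (bound / 3)^2)),
    class = "directional_prior"
  )
}

#' @export
print.directional_prior <- function(x, ...) {
  cat(sprintf(
    "<directional_prior> alpha_hat = %.4g, beta_hat = %.4g, bound = %.4g\n  rho ~ Gamma(shape = %.2g, rate = %.4g)\n",
    x$alpha_hat, x$beta_hat, x$bound, x$shape, x$rate
  ))
  invisible(x)
}
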