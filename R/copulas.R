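#' Parameters of the Rodriguez-Lallena--Ubeda-Flores (RLUF) copula
#'
#' The RLUF family is the perturbation of the independence copula
#' \deqn{C(u, v) = uv + \vartheta\, u v (1-u)^\alpha (1-v)^\beta,}
#' with association parameter \eqn{\vartheta} and asymmetry parameters
#' \eqn{\alpha, \beta > 1}. The copula is asymmetric whenever
#' \eqn{\alpha \neq \beta}, which is what lets it encode a *directional*
#' (rather than merely mutual) dependence between the two margins.
#'
#' @param theta_assoc association parameter \eqn{\vartheta}; must lie within
#'   the admissibility bound for `(alpha, beta)` (see
#'   [admissibility_bound()]) for the function to be a valid copula.
#' @param alpha,beta asymmetry parameters, both strictly greater than 1.
#' @return An object of class `rluf_params`.
#' @seealso [rluf_cdf()], [admissibility_bound()], [rho_closed_form()]
#' @export
#' @examples
#' p <- rluf_params(0.5, 2, 3)
#' rluf_cdf(0.5, 0.5, p)
rluf_params <- function(theta_assoc, alpha, beta) {
  stopifnot(is.numeric(theta_assoc), is.numeric(alpha), is.numeric(beta))
  if (alpha <= 1 || beta <= 1) {
    stop("RLUF asymmetry parameters must satisfy alpha > 1 and beta > 1.")
  }
  bnd <- admissibility_bound(alpha, beta)
  if (abs(theta_assoc) > bnd + 1e-12) {
    stop(sprintf(
      "theta_assoc = %g violates the admissibility bound %.6g for (alpha, beta) = (%g, %g).",
      theta_assoc, bnd, alpha, beta
    ))
  }
  structure(
    list(theta_assoc = theta_assoc, alpha = alpha, beta = beta),
    class = "rluf_params"
  )
}

#' Parameters of the Tawn extreme-value copula
#'
#' The Tawn copula is the extreme-value copula with Pickands dependence
#' function
#' \deqn{A(t) = (1-\psi_1)(1-t) + (1-\psi_2)t +
#'   [(\psi_1(1-t))^\theta + (\psi_2 t)^\theta]^{1/\theta}.}
#' Type 1 fixes \eqn{\psi_2 = 1}, Type 2 fixes \eqn{\psi_1 = 1}; with
#' \eqn{\psi_1 \neq \psi_2} the copula is asymmetric.
#'
#' @param psi1,psi2 asymmetry weights in \eqn{[0, 1]}.
#' @param theta_ev extreme-value dependence parameter, \eqn{\ge 1}.
#' @return An object of class `tawn_params`.
#' @export
tawn_params <- function(psi1, psi2, theta_ev) {
  stopifnot(is.numeric(psi1), is.numeric(psi2), is.numeric(theta_ev))
  if (psi1 < 0 || psi1 > 1 || psi2 < 0 || psi2 > 1) {
    stop("psi1 and psi2 must lie in [0, 1].")
  }
  if (theta_ev < 1) stop("theta_ev must be >= 1.")
  structure(
    list(psi1 = psi1, psi2 = psi2, theta_ev = theta_ev),
    class = "tawn_params"
  )
}

#' Parameters of the BB1 copula
#'
#' Two-parameter Archimedean family with generator
#' \eqn{\phi(t) = (t^{-\theta} - 1)^\delta}, allowing both lower and upper
#' tail dependence.
#'
#' @param theta positive dependence parameter.
#' @param delta dependence parameter, \eqn{\ge 1}.
#' @return An object of class `bb1_params`.
#' @export
bb1_params <- function(theta, delta) {
  if (theta <= 0) stop("BB1 theta must be > 0.")
  if (delta < 1) stop("BB1 delta must be >= 1.")
  structure(list(theta = theta, delta = delta), class = "bb1_params")
}

#' Uniform handle on a bivariate copula
#'
#' Bundles a copula family, its parameters, and a declaration of which margin
#' is "upstream" (the explanatory margin of the directional relationship).
#' This is the single currency passed to [sample_copula()],
#' [rho_from_regression()] and the synthetic-data generator.
#'
#' @param family one of `"rluf"`, `"tawn1"`, `"tawn2"`, `"bb1"`,
#'   `"independence"`.
#' @param params family parameter object ([rluf_params()], [tawn_params()],
#'   [bb1_params()]); ignored for `"independence"`. For `"tawn1"` the
#'   constraint `psi2 == 1` is enforced, for `"tawn2"` `psi1 == 1`.
#' @param direction which margin is upstream: `"v_to_u"` (V explains U,
#'   the default) or `"u_to_v"`.
#' @return An object of class `copula_spec`.
#' @export
#' @examples
#' spec <- copula_spec("tawn1", tawn_params(0.5, 1, 30))
#' sample_copula(spec, 5, seed = 1)
copula_spec <- function(family = c("rluf", "tawn1", "tawn2", "bb1", "independence"),
                        params = NULL,
                        direction = c("v_to_u", "u_to_v")) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  if (family %in% c("tawn1", "tawn2")) {
    if (!inherits(params, "tawn_params")) stop("tawn families need tawn_params().")
    if (family == "tawn1" && params$psi2 != 1) {
      stop("Tawn Type 1 requires psi2 = 1.")
    }
    if (family == "tawn2" && params$psi1 != 1) {
      stop("Tawn Type 2 requires psi1 = 1.")
    }
  } else if (family == "rluf") {
    if (!inherits(params, "rluf_params")) stop("rluf family needs rluf_params().")
  } else if (family == "bb1") {
    if (!inherits(params, "bb1_params")) stop("bb1 family needs bb1_params().")
  }
  structure(
    list(family = family, params = params, direction = direction),
    class = "copula_spec"
  )
}

#' @export
print.copula_spec <- function(x, ...) {
  cat("<copula_spec> family:", x$family, " upstream margin:",
      if (x$direction == "v_to_u") "v" else "u", "\n")
  if (!is.null(x$params)) utils::str(unclass(x$params), give.head = FALSE)
  invisible(x)
}

# clamp into the open unit interval before log transforms
.clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

#' RLUF copula distribution function
#'
#' @param u,v evaluation points in \eqn{[0, 1]} (vectorized, recycled).
#' @param p an [rluf_params()] object.
#' @return `C(u, v)` values.
#' @export
rluf_cdf <- function(u, v, p) {
  stopifnot(inherits(p, "rluf_params"))
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) stop("u, v must lie in [0, 1].")
  u * v + p$theta_assoc * u * v * (1 - u)^p$alpha * (1 - v)^p$beta
}

#' Conditional distribution of the RLUF copula
#'
#' `C_{U|V}(u | v) = dC(u, v)/dv` when `given = "v"`, and the mirrored
#' `C_{V|U}(v | u) = dC(u, v)/du` when `given = "u"`. Values are clamped to
#' \eqn{[0, 1]} only when within numerical tolerance of the bounds.
#'
#' @inheritParams rluf_cdf
#' @param given the conditioning margin, `"v"` or `"u"`.
#' @return conditional probabilities in \eqn{[0, 1]}.
#' @export
rluf_conditional <- function(u, v, p, given = c("v", "u")) {
  stopifnot(inherits(p, "rluf_params"))
  given <- match.arg(given)
  th <- p$theta_assoc; a <- p$alpha; b <- p$beta
  out <- if (given == "v") {
    u + th * u * (1 - u)^a * ((1 - v)^b - b * v * (1 - v)^(b - 1))
  } else {
    v + th * v * (1 - v)^b * ((1 - u)^a - a * u * (1 - u)^(a - 1))
  }
  tol <- 1e-9
  out[out < 0 & out > -tol] <- 0
  out[out > 1 & out < 1 + tol] <- 1
  out
}

#' Pickands dependence function of the Tawn copula
#'
#' @param t evaluation points in \eqn{[0, 1]} (vectorized).
#' @param p a [tawn_params()] object.
#' @return `A(t)`, satisfying `max(t, 1-t) <= A(t) <= 1`.
#' @export
tawn_pickands <- function(t, p) {
  stopifnot(inherits(p, "tawn_params"))
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1].")
  (1 - p$psi1) * (1 - t) + (1 - p$psi2) * t +
    ((p$psi1 * (1 - t))^p$theta_ev + (p$psi2 * t)^p$theta_ev)^(1 / p$theta_ev)
}

# derivative of the Pickands function, used by the analytic conditional
tawn_pickands_deriv <- function(t, p) {
  th <- p$theta_ev
  g <- (p$psi1 * (1 - t))^th + (p$psi2 * t)^th
  -(1 - p$psi1) + (1 - p$psi2) +
    ifelse(g > 0,
           g^(1 / th - 1) *
             (-p$psi1 * (p$psi1 * (1 - t))^(th - 1) +
                p$psi2 * (p$psi2 * t)^(th - 1)),
           0)
}

#' Tawn copula distribution function
#'
#' Extreme-value form
#' \eqn{C(u,v) = \exp\{(\log u + \log v)\, A(\log v / (\log u + \log v))\}}.
#'
#' @inheritParams rluf_cdf
#' @param p a [tawn_params()] object.
#' @return `C(u, v)` values; the limit 0 is returned when `u` or `v` is 0.
#' @export
tawn_cdf <- function(u, v, p) {
  stopifnot(inherits(p, "tawn_params"))
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) stop("u, v must lie in [0, 1].")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- numeric(n)
  zero <- u == 0 | v == 0
  uc <- .clamp01(u[!zero]); vc <- .clamp01(v[!zero])
  s <- log(uc) + log(vc)
  t <- log(vc) / s
  out[!zero] <- exp(s * tawn_pickands(t, p))
  out
}

# dC(u, v)/dv for the Tawn copula:
# with s = log u + log v, t = log v / s,
# dC/dv = C(u,v)/v * (A(t) + (1 - t) A'(t)).
tawn_conditional_v <- function(u, v, p) {
  uc <- .clamp01(u); vc <- .clamp01(v)
  s <- log(uc) + log(vc)
  t <- log(vc) / s
  Cuv <- exp(s * tawn_pickands(t, p))
  out <- Cuv / vc * (tawn_pickands(t, p) + (1 - t) * tawn_pickands_deriv(t, p))
  pmin(pmax(out, 0), 1)
}

#' BB1 copula distribution function
#'
#' @inheritParams rluf_cdf
#' @param p a [bb1_params()] object.
#' @return `C(u, v)` values.
#' @export
bb1_cdf <- function(u, v, p) {
  stopifnot(inherits(p, "bb1_params"))
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) stop("u, v must lie in [0, 1].")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- numeric(n)
  zero <- u == 0 | v == 0
  uc <- .clamp01(u[!zero]); vc <- .clamp01(v[!zero])
  th <- p$theta; de <- p$delta
  w <- ((uc^(-th) - 1)^de + (vc^(-th) - 1)^de)^(1 / de)
  out[!zero] <- (1 + w)^(-1 / th)
  out
}

# dispatch: C(u, v) for a copula_spec
copula_cdf <- function(u, v, spec) {
  switch(spec$family,
    independence = u * v,
    rluf = rluf_cdf(u, v, spec$params),
    tawn1 = ,
    tawn2 = tawn_cdf(u, v, spec$params),
    bb1 = bb1_cdf(u, v, spec$params),
    stop("unknown copula family: ", spec$family)
  )
}

# conditional C_{U|V}(u | v) = dC/dv, analytic where cheap, central
# difference otherwise; vectorized over u (v may recycle)
copula_conditional_v <- function(u, v, spec, h = 1e-6) {
  switch(spec$family,
    independence = rep_len(u, max(length(u), length(v))),
    rluf = rluf_conditional(u, v, spec$params, given = "v"),
    tawn1 = ,
    tawn2 = tawn_conditional_v(u, v, spec$params),
    {
      vc <- .clamp01(v, eps = 2 * h)
      out <- (copula_cdf(u, vc + h, spec) - copula_cdf(u, vc - h, spec)) / (2 * h)
      pmin(pmax(out, 0), 1)
    }
  )
}

# mirror: C_{V|U}(v | u) = dC(u, v)/du, via the swapped copula
copula_conditional_u <- function(u, v, spec, h = 1e-6) {
  sw <- swap_copula(spec)
  copula_conditional_v(v, u, sw, h = h)
}

# the copula of (V, U) when spec is the copula of (U, V)
swap_copula <- function(spec) {
  params <- spec$params
  family <- spec$family
  if (family %in% c("tawn1", "tawn2")) {
    params <- tawn_params(psi1 = params$psi2, psi2 = params$psi1,
                          theta_ev = params$theta_ev)
    family <- if (family == "tawn1") "tawn2" else "tawn1"
  } else if (family == "rluf") {
    params <- rluf_params(params$theta_assoc, alpha = params$beta,
                          beta = params$alpha)
  }
  structure(list(family = family, params = params,
                 direction = if (spec$direction == "v_to_u") "u_to_v" else "v_to_u"),
            class = "copula_spec")
}

#' Draw paired uniform scores from a copula
#'
#' Sampling is by conditional-distribution inversion: the upstream margin is
#' drawn uniform, then the downstream value solves
#' \eqn{C_{\cdot|\cdot}(x \mid \text{upstream}) = w} by bisection to
#' tolerance `1e-10`. Exact for every supported family; no rejection step.
#'
#' @param spec a [copula_spec()].
#' @param n number of pairs.
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @return A tibble with columns `u` and `v`, each marginally uniform on
#'   \eqn{(0, 1)} and jointly distributed according to `spec`.
#' @export
#' @examples
#' sc <- sample_copula(copula_spec("tawn1", tawn_params(0.5, 1, 30)), 100, seed = 7)
#' cor(sc$u, sc$v, method = "kendall")
sample_copula <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  w1 <- stats::runif(n)
  w2 <- stats::runif(n)
  if (spec$family == "independence") {
    return(tibble::tibble(u = w1, v = w2))
  }
  if (spec$direction == "v_to_u") {
    v <- w1
    u <- invert_conditional(function(x) copula_conditional_v(x, v, spec), w2, n)
  } else {
    u <- w1
    v <- invert_conditional(function(x) copula_conditional_u(u, x, spec), w2, n)
  }
  tibble::tibble(u = u, v = v)
}

# vectorized bisection: solve cond(x) = w for x in (0, 1), cond nondecreasing
invert_conditional <- function(cond, w, n, tol = 1e-10, max_iter = 60) {
  lo <- rep(0, n); hi <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- cond(mid)
    below <- f < w
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}
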