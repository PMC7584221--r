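#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the posterior of the dependence strengths
#'
#' One row per directional edge with posterior summaries of
#' \eqn{\rho_{m \to k}}.
#'
#' @param x a [dirclust()] fit.
#' @param ... unused.
#' @return tibble with columns `from`, `to`, `estimate` (posterior mean),
#'   `std.error`, `conf.low`, `conf.high` (central 95%), `prior_rate`.
#' @export
tidy.dirclust_fit <- function(x, ...) {
  ed <- x$graph$edges
  if (!nrow(ed)) {
    return(tibble::tibble(from = character(), to = character(),
                          estimate = numeric(), std.error = numeric(),
                          conf.low = numeric(), conf.high = numeric(),
                          prior_rate = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(ed)), function(e) {
    draws <- x$rho_chain[, e]
    tibble::tibble(
      from = ed$from[e], to = ed$to[e],
      estimate = mean(draws), std.error = stats::sd(draws),
      conf.low = unname(stats::quantile(draws, 0.025)),
      conf.high = unname(stats::quantile(draws, 0.975)),
      prior_rate = x$priors[[e]]$rate
    )
  })
}

#' One-line summary of a fit
#'
#' @param x a [dirclust()] fit.
#' @param ... unused.
#' @return one-row tibble: `n`, `views`, `K`, `retained`,
#'   `consensus_view`, `clusters_modal`, `clusters_mean`, `mean_xi`.
#' @export
glance.dirclust_fit <- function(x, ...) {
  occ <- occupied_clusters(x)
  tibble::tibble(
    n = x$N, views = x$M, K = x$K, retained = length(x$xi_chain),
    consensus_view = x$graph$terminal,
    clusters_modal = occ$mode, clusters_mean = occ$mean,
    mean_xi = mean(x$xi_chain)
  )
}

#' Heatmap of the posterior similarity matrix
#'
#' Objects are ordered by consensus label so co-clustering blocks are
#' visible.
#'
#' @param object a [dirclust()] fit.
#' @param view view to display (default: terminal/consensus view).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dirclust_fit <- function(object, view = NULL, ...) {
  S <- similarity_matrix(object, view)
  ord <- order(consensus_labels(object, view))
  S <- S[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(S)), j = seq_len(ncol(S)))
  df$probability <- S[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "P(same cluster)",
                  title = "Posterior similarity") +
    ggplot2::theme_minimal()
}

#' Accuracy-by-condition plot for a replicated experiment
#'
#' @param runs output of [reproduce_simulation()].
#' @return a ggplot object.
#' @export
plot_experiment <- function(runs) {
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$case, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::facet_grid(family ~ n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "consensus accuracy") +
    ggplot2::theme_minimal()
}
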