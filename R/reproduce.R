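#' Run replicated simulation experiments
#'
#' Scripted reproduction of the simulation study: generates scenario data,
#' fits the model, and scores the consensus clustering against ground truth,
#' over a grid of cases, generator copula families and sample sizes, with
#' `n_runs` independent replicates per grid cell. Per-run seeds are derived
#' deterministically from `seed` and recorded in the output.
#'
#' @param experiment one of `"cases"` (three directionality conditions at
#'   the default generator), `"copula_sweep"` (Tawn Type 1 / Type 2 / BB1
#'   by case) or `"samplesize_sweep"` (n in 250, 500, 750 by case); or
#'   `"custom"` to use the `cases`, `families`, `sizes` arguments as given.
#' @param n_runs replicates per condition (default 10).
#' @param seed master seed; per-run seeds are drawn from it.
#' @param iterations,burn_in Gibbs schedule (defaults 2000 and half).
#' @param cases,families,sizes grids used when `experiment = "custom"`.
#' @param K cluster-count upper bound; `NULL` (default) uses
#'   \eqn{\lceil N/2 \rceil}.
#' @param verbose print one line per completed run.
#' @return tibble with one row per run: `case`, `family`, `n`, `run`,
#'   `seed`, `accuracy`, `rand`, `n_clusters_modal`, `n_clusters_mean`,
#'   `elapsed`.
#' @export
reproduce_simulation <- function(experiment = c("cases", "copula_sweep",
                                                "samplesize_sweep", "custom"),
                                 n_runs = 10, seed = 1,
                                 iterations = 2000,
                                 burn_in = floor(iterations / 2),
                                 cases = "true_direction",
                                 families = "tawn1", sizes = 500,
                                 K = NULL, verbose = FALSE) {
  experiment <- match.arg(experiment)
  all_cases <- c("true_direction", "no_direction", "reversed")
  grid <- switch(experiment,
    cases = expand.grid(case = all_cases, family = "tawn1", n = 500,
                        stringsAsFactors = FALSE),
    copula_sweep = expand.grid(case = all_cases,
                               family = c("tawn1", "tawn2", "bb1"), n = 500,
                               stringsAsFactors = FALSE),
    samplesize_sweep = expand.grid(case = all_cases, family = "tawn1",
                                   n = c(250, 500, 750),
                                   stringsAsFactors = FALSE),
    custom = expand.grid(case = cases, family = families, n = sizes,
                         stringsAsFactors = FALSE)
  )
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max %/% 2L, n_runs)
  rows <- purrr::pmap(grid, function(case, family, n) {
    purrr::map(seq_len(n_runs), function(r) {
      t0 <- proc.time()[["elapsed"]]
      sc <- simulation_scenario(case, family = family, n = n,
                                seed = run_seeds[r])
      fit <- dirclust(sc$views, sc$graph, K = K,
                      iterations = iterations, burn_in = burn_in,
                      seed = run_seeds[r])
      est <- consensus_labels(fit)
      occ <- occupied_clusters(fit)
      out <- tibble::tibble(
        case = case, family = family, n = n, run = r,
        seed = run_seeds[r],
        accuracy = clustering_accuracy(sc$labels, est),
        rand = rand_index(sc$labels, est),
        n_clusters_modal = occ$mode,
        n_clusters_mean = occ$mean,
        elapsed = proc.time()[["elapsed"]] - t0
      )
      if (verbose) {
        message(sprintf("%s/%s n=%d run %d: acc %.3f, clusters %d",
                        case, family, n, r, out$accuracy,
                        out$n_clusters_modal))
      }
      out
    })
  })
  dplyr::bind_rows(rows)
}

#' Summarize a replicated experiment table
#'
#' Mean accuracy and cluster counts per condition, in the layout of the
#' simulation-study tables.
#'
#' @param runs output of [reproduce_simulation()].
#' @return tibble with one row per (case, family, n).
#' @export
summarize_runs <- function(runs) {
  runs |>
    dplyr::group_by(.data$case, .data$family, .data$n) |>
    dplyr::summarize(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      mean_clusters = mean(.data$n_clusters_modal),
      modal_clusters = as.integer(names(which.max(
        table(.data$n_clusters_modal)))),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}
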