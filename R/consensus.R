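# Label alignment across MCMC iterations.
#
# Cluster labels are only identified up to permutation within each sweep, so
# before summarizing a chain the labels of every retained iteration are
# aligned to a reference iteration by Hungarian matching on the contingency
# table (maximum agreement). Labels with no match in the reference (extra
# clusters) keep fresh identities.
align_to_reference <- function(lab, ref) {
  lt <- sort(unique(lab))
  lr <- sort(unique(ref))
  n <- max(length(lt), length(lr))
  cost <- matrix(0, n, n)
  cost[seq_along(lt), seq_along(lr)] <-
    unclass(table(factor(lab, lt), factor(ref, lr)))
  sol <- as.integer(clue::solve_LSAP(cost, maximum = TRUE))
  map <- integer(length(lt))
  extra <- max(lr)
  for (j in seq_along(lt)) {
    if (sol[j] <= length(lr)) {
      map[j] <- lr[sol[j]]
    } else {
      extra <- extra + 1L
      map[j] <- extra
    }
  }
  map[match(lab, lt)]
}

#' Consensus labels from a fitted chain
#'
#' The terminal (consensus) view's partition: for each retained iteration
#' the terminal-view allocations are aligned to a reference iteration by
#' Hungarian matching, then each object receives its modal aligned label
#' across iterations (maximum a posteriori under the aligned chain).
#'
#' @param fit a [dirclust()] fit.
#' @param view view to summarize; defaults to the graph's terminal view.
#' @return integer label vector of length N.
#' @export
consensus_labels <- function(fit, view = NULL) {
  ch <- view_chain(fit, view)
  Tn <- nrow(ch)
  ref <- ch[1, ]
  aligned <- matrix(0L, Tn, ncol(ch))
  aligned[1, ] <- ref
  if (Tn > 1) {
    for (t in 2:Tn) aligned[t, ] <- align_to_reference(ch[t, ], ref)
  }
  apply(aligned, 2, function(col) {
    tab <- tabulate(col)
    which.max(tab)
  })
}

#' Posterior similarity matrix
#'
#' Entry (i, j) is the fraction of retained iterations in which objects i
#' and j share a cluster in the given view -- the posterior probability of
#' co-clustering. Symmetric with unit diagonal; invariant to label
#' switching, so no alignment is needed.
#'
#' @inheritParams consensus_labels
#' @return N x N numeric matrix.
#' @export
similarity_matrix <- function(fit, view = NULL) {
  ch <- view_chain(fit, view)
  similarity_cpp(ch)
}

#' Occupied-cluster counts of a view's chain
#'
#' @inheritParams consensus_labels
#' @return list with `counts` (per retained iteration), `mode`, `mean`.
#' @export
occupied_clusters <- function(fit, view = NULL) {
  ch <- view_chain(fit, view)
  counts <- apply(ch, 1, function(x) length(unique(x)))
  tab <- table(counts)
  list(counts = as.integer(counts),
       mode = as.integer(names(tab)[which.max(tab)]),
       mean = mean(counts))
}
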