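#' Permutation-matched clustering accuracy
#'
#' Maximum over label matchings (Hungarian assignment on the contingency
#' table) of the fraction of agreeing objects. Invariant to relabeling of
#' either argument; when the estimate uses more clusters than the truth,
#' the unmatched clusters count entirely as errors.
#'
#' @param truth,estimate integer (or factor) label vectors of equal length.
#' @return accuracy in \eqn{[0, 1]}.
#' @export
#' @examples
#' clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: relabeling
#' clustering_accuracy(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 0.5
clustering_accuracy <- function(truth, estimate) {
  truth <- as.integer(as.factor(truth))
  estimate <- as.integer(as.factor(estimate))
  if (length(truth) != length(estimate)) stop("label vectors differ in length.")
  lt <- sort(unique(estimate)); lr <- sort(unique(truth))
  n <- max(length(lt), length(lr))
  cost <- matrix(0, n, n)
  cost[seq_along(lt), seq_along(lr)] <-
    unclass(table(factor(estimate, lt), factor(truth, lr)))
  sol <- clue::solve_LSAP(cost, maximum = TRUE)
  sum(cost[cbind(seq_len(n), as.integer(sol))]) / length(truth)
}

#' Rand index
#'
#' Fraction of object pairs on which two partitions agree (both place the
#' pair together, or both apart). Label-free: invariant to relabeling of
#' either argument.
#'
#' @param a,b label vectors of equal length \eqn{\ge 2}.
#' @return value in \eqn{[0, 1]}.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 1/3
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length.")
  n <- length(a)
  if (n < 2) stop("need at least 2 objects.")
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_ij - s_a - s_b) / total
}
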