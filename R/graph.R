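#' Directed dependency graph over data types
#'
#' Encodes the known directional dependencies among views (for genomic data,
#' the central dogma: e.g. gene expression -> protein) as a directed acyclic
#' graph, plus the designation of the terminal view whose clustering is
#' reported as the consensus (for omics data, the protein view, being
#' closest to the phenotype).
#'
#' @param nodes character vector of view names, in the order of the data
#'   list handed to the sampler.
#' @param edges two-column matrix or data frame of ordered pairs
#'   `(from, to)`, meaning "from" is directionally upstream of "to". May be
#'   empty (`NULL`) for independent per-view clustering.
#' @param terminal the consensus view; must be a sink (no outgoing edge).
#'   Defaults to the unique sink when there is exactly one, otherwise the
#'   last node.
#' @return An object of class `dependency_graph`.
#' @export
#' @examples
#' dependency_graph(c("GE", "miRNA", "RPPA"),
#'                  edges = rbind(c("GE", "RPPA"), c("GE", "miRNA"),
#'                                c("miRNA", "RPPA")))
dependency_graph <- function(nodes, edges = NULL, terminal = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges <- tibble::as_tibble(edges)
  }
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints must be listed in `nodes`.")
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed.")
  if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate edges.")
  if (has_cycle(nodes, edges)) stop("dependency graph must be acyclic.")
  sinks <- setdiff(nodes, edges$from)
  if (is.null(terminal)) {
    terminal <- if (length(sinks) == 1) sinks else nodes[length(nodes)]
  }
  if (!terminal %in% nodes) stop("terminal must be one of the nodes.")
  if (!terminal %in% sinks) {
    stop("terminal view must be a sink (no outgoing directional edge).")
  }
  structure(list(nodes = nodes, edges = edges, terminal = terminal),
            class = "dependency_graph")
}

has_cycle <- function(nodes, edges) {
  # Kahn's algorithm
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (to in edges$to) indeg[to] <- indeg[to] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges$to[edges$from == n]
    for (to in out) {
      indeg[to] <- indeg[to] - 1L
      if (indeg[to] == 0L) queue <- c(queue, to)
    }
  }
  seen < length(nodes)
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("<dependency_graph>", length(x$nodes), "views:",
      paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(paste(x$edges$from, "->", x$edges$to),
                          collapse = "; "), "\n")
  } else {
    cat("  edges: none (independent views)\n")
  }
  cat("  consensus (terminal) view:", x$terminal, "\n")
  invisible(x)
}

# integer edge matrix (E x 2) in node order; E may be 0
edge_index_matrix <- function(graph) {
  m <- cbind(match(graph$edges$from, graph$nodes),
             match(graph$edges$to, graph$nodes))
  storage.mode(m) <- "integer"
  m
}

#' Read / write a dependency graph as JSON
#'
#' The on-disk format is a JSON object with fields `nodes`, `edges` (array
#' of `[from, to]` pairs) and `terminal`.
#'
#' @param path file path.
#' @return `read_graph_json()` returns a [dependency_graph()];
#'   `write_graph_json()` returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) {
    if (is.matrix(obj$edges)) obj$edges
    else matrix(unlist(obj$edges), ncol = 2, byrow = TRUE)
  } else NULL
  dependency_graph(obj$nodes, edges = edges, terminal = obj$terminal)
}

#' @rdname read_graph_json
#' @param graph a [dependency_graph()].
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes,
         edges = unname(as.matrix(graph$edges)),
         terminal = graph$terminal),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
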