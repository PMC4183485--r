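# Undirected simple graphs with opaque string node labels. Node order is
# insertion order so that every matrix view is reproducible run to run.

new_network <- function(nodes, edges, weights) {
  structure(list(nodes = nodes, edges = edges, weights = weights),
            class = "carto_network")
}

#' Build an undirected network from an edge list
#'
#' Nodes are case-sensitive string labels kept in first-seen order: any
#' labels passed through `nodes` come first, then edge endpoints in the
#' order they appear. Repeated edges and the two orientations of the same
#' pair collapse silently to one undirected edge (first weight wins);
#' self-loops are dropped with a warning. Edge weights, when present, are
#' stored for export only — the clustering and cartography routines always
#' work on the unweighted adjacency matrix.
#'
#' @param edges two-column character matrix or data frame of endpoint
#'   labels; may be `NULL` or empty.
#' @param nodes optional character vector of node labels placed first in
#'   the node order; use it to declare isolated nodes, which an edge list
#'   alone cannot represent.
#' @param weights optional numeric vector with one entry per row of
#'   `edges` (`NA` for unweighted rows).
#' @return An object of class `carto_network` with fields `nodes`
#'   (character vector), `edges` (two-column character matrix) and
#'   `weights` (numeric vector or `NULL`).
#' @examples
#' net <- network(rbind(c("A", "B"), c("B", "C")))
#' adjacency_matrix(net)
#' @export
network <- function(edges = NULL, nodes = NULL, weights = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    mode(edges) <- "character"
  }
  if (ncol(edges) != 2) stop("edges must have exactly two columns")
  if (!is.null(nodes)) nodes <- as.character(nodes)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(edges))
      stop("weights must have one entry per edge")
    if (all(is.na(weights))) weights <- NULL
  }
  loop <- edges[, 1] == edges[, 2]
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loop)))
    edges <- edges[!loop, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!loop]
  }
  node_order <- unique(c(nodes, as.vector(t(edges))))
  if (nrow(edges)) {
    i <- match(edges[, 1], node_order)
    j <- match(edges[, 2], node_order)
    u <- pmin(i, j)
    v <- pmax(i, j)
    keep <- !duplicated(cbind(u, v))
    edges <- cbind(node_order[u[keep]], node_order[v[keep]])
    if (!is.null(weights)) weights <- weights[keep]
  }
  dimnames(edges) <- NULL
  new_network(node_order, edges, weights)
}

#' Number of nodes / edges in a network
#' @param net a `carto_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.carto_network <- function(x, ...) {
  cat(sprintf("<network: %d nodes, %d edges%s>\n",
              n_nodes(x), n_edges(x),
              if (!is.null(x$weights)) ", weighted" else ""))
  invisible(x)
}

#' Convert a network to an igraph graph
#'
#' Vertex order follows the network's node order. Weights are attached as
#' an edge attribute only when `weighted = TRUE`; the default keeps the
#' graph unweighted so path computations treat every edge equally.
#'
#' @param net a `carto_network`
#' @param weighted attach stored edge weights as the `weight` attribute?
#' @return an [igraph::graph] object
#' @export
as_igraph <- function(net, weighted = FALSE) {
  vdf <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  edf <- data.frame(from = net$edges[, 1], to = net$edges[, 2],
                    stringsAsFactors = FALSE)
  if (weighted && !is.null(net$weights)) edf$weight <- net$weights
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Adjacency matrix of a network
#'
#' @param net a `carto_network`; must contain at least one node.
#' @param weighted if `TRUE`, entries carry the stored edge weight
#'   (missing weights fall back to 1); the unweighted binary view is the
#'   one every clustering engine consumes.
#' @return symmetric numeric matrix with zero diagonal, rows and columns
#'   in node order.
#' @export
adjacency_matrix <- function(net, weighted = FALSE) {
  n <- n_nodes(net)
  if (n == 0) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net)) {
    i <- match(net$edges[, 1], net$nodes)
    j <- match(net$edges[, 2], net$nodes)
    w <- 1
    if (weighted && !is.null(net$weights)) {
      w <- ifelse(is.na(net$weights), 1, net$weights)
    }
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Node degrees
#'
#' @param net a `carto_network`
#' @return named integer vector (node order), counting incident edges;
#'   the values sum to twice the edge count.
#' @export
degrees <- function(net) {
  d <- setNames(integer(n_nodes(net)), net$nodes)
  if (n_edges(net)) {
    tab <- table(factor(as.vector(net$edges), levels = net$nodes))
    d[] <- as.integer(tab)
  }
  d
}

#' Connected components
#'
#' @param net a `carto_network`
#' @return list of character vectors partitioning the node set; two nodes
#'   share a component iff a path joins them.
#' @export
connected_components <- function(net) {
  if (n_nodes(net) == 0) return(list())
  memb <- igraph::components(as_igraph(net))$membership
  unname(split(net$nodes, memb[net$nodes]))
}
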