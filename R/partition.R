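# Total node -> module assignments. Module labels are opaque strings kept
# in first-seen order; internal indices are contiguous.

#' Create a module partition
#'
#' @param assignment named vector: names are node labels, values module
#'   labels. Module labels are opaque strings; their first-seen order
#'   defines the contiguous internal module indices.
#' @return an object of class `carto_partition` with fields `nodes`,
#'   `labels` (named character, node -> module label) and `module_labels`.
#' @examples
#' p <- partition(c(A = "1", B = "1", C = "2"))
#' modules(p)
#' @export
partition <- function(assignment) {
  nodes <- names(assignment)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("assignment must be named by node label")
  if (anyDuplicated(nodes))
    stop("duplicate node label in assignment: ",
         nodes[duplicated(nodes)][1])
  labels <- as.character(assignment)
  if (anyNA(labels)) stop("missing module label")
  structure(list(nodes = nodes,
                 labels = setNames(labels, nodes),
                 module_labels = unique(labels)),
            class = "carto_partition")
}

#' Number of modules in a partition
#' @param p a `carto_partition`
#' @return integer
#' @export
n_modules <- function(p) length(p$module_labels)

#' Module node sets
#' @param p a `carto_partition`
#' @return named list of character vectors, one per module, in first-seen
#'   module order.
#' @export
modules <- function(p) {
  split(p$nodes, factor(p$labels, levels = p$module_labels))
}

#' Contiguous module indices
#' @param p a `carto_partition`
#' @return named integer vector mapping each node to its module's
#'   contiguous index (1..N, first-seen order).
#' @export
module_index <- function(p) {
  setNames(match(p$labels, p$module_labels), p$nodes)
}

#' @export
print.carto_partition <- function(x, ...) {
  sizes <- lengths(modules(x))
  cat(sprintf("<partition: %d nodes in %d modules (sizes %s)>\n",
              length(x$nodes), n_modules(x),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

# A partition is usable with a network only if it covers exactly its nodes.
check_partition <- function(net, p) {
  missing <- setdiff(net$nodes, p$nodes)
  if (length(missing))
    stop("partition is missing node(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(p$nodes, net$nodes)
  if (length(extra))
    stop("partition names node(s) absent from the network: ",
         paste(utils::head(extra, 5), collapse = ", "))
  invisible(TRUE)
}
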