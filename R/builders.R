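# Network constructors: protein contact maps, co-expression graphs, and
# reference random models (Erdos-Renyi G(n,m), Barabasi-Albert, planted
# partition).

#' Protein contact network from alpha-carbon coordinates
#'
#' Residues become nodes; an edge joins two residues whose Euclidean
#' alpha-carbon distance lies in the closed window `[d_min, d_max]`
#' Angstrom. The default 4-8 window keeps non-covalent intramolecular
#' contacts only: consecutive backbone CA atoms sit near 3.8 A, below the
#' lower bound, so no sequence-separation filter is needed. Every residue
#' becomes a node even when isolated.
#'
#' @param residues data frame with columns `label`, `x`, `y`, `z`, e.g.
#'   from [read_pdb_ca()]; labels must be unique
#' @param d_min,d_max distance window in Angstrom, closed on both ends
#' @return a [network()] over the residue labels
#' @export
contact_network <- function(residues, d_min = 4, d_max = 8) {
  stopifnot(d_min >= 0, d_min < d_max)
  labels <- as.character(residues$label)
  if (anyDuplicated(labels))
    stop("duplicate residue labels: ", labels[duplicated(labels)][1])
  if (length(labels) < 2) stop("need at least two residues")
  D <- as.matrix(dist(as.matrix(residues[, c("x", "y", "z")])))
  sel <- which(upper.tri(D) & D >= d_min & D <= d_max, arr.ind = TRUE)
  network(cbind(labels[sel[, 1]], labels[sel[, 2]]), nodes = labels)
}

#' Gene co-expression network from an expression matrix
#'
#' Links two genes when the absolute Pearson correlation of their
#' expression profiles strictly exceeds `threshold`. Correlations use
#' pairwise-complete samples; pairs with fewer than 3 complete samples are
#' skipped with a warning, and zero-variance genes (undefined r) produce
#' no edges. Every gene becomes a node.
#'
#' @param expr an [expression_matrix()]
#' @param threshold absolute correlation cut in (0, 1]
#' @return a [network()] over the gene labels
#' @export
coexpression_network <- function(expr, threshold = 0.8) {
  stopifnot(inherits(expr, "expression_matrix"),
            threshold > 0, threshold <= 1)
  V <- expr$values
  if (ncol(V) < 2) stop("need at least two samples")
  R <- suppressWarnings(cor(t(V), use = "pairwise.complete.obs"))
  obs <- (!is.na(V)) %*% t(!is.na(V))
  few <- obs < 3
  n_few <- sum(few[upper.tri(few)])
  if (n_few)
    warning(sprintf(
      "%d gene pair(s) with fewer than 3 complete samples skipped", n_few))
  R[few] <- NA
  sel <- which(upper.tri(R) & !is.na(R) & abs(R) > threshold,
               arr.ind = TRUE)
  network(cbind(expr$genes[sel[, 1]], expr$genes[sel[, 2]]),
          nodes = expr$genes)
}

#' Erdos-Renyi G(n, m) random network
#'
#' Samples exactly `m` distinct edges uniformly among the `choose(n, 2)`
#' possible pairs (fixed edge count, not fixed probability). Reproducible
#' for a given seed.
#'
#' @param n number of nodes (labelled `n1..n<n>`)
#' @param m number of edges
#' @param seed optional RNG seed
#' @return a [network()]
#' @export
erdos_renyi_gm <- function(n, m, seed = NULL) {
  stopifnot(n >= 1, m >= 0)
  if (m > n * (n - 1) / 2)
    stop("m exceeds the maximum n(n-1)/2 = ", n * (n - 1) / 2)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  el <- igraph::as_edgelist(g, names = FALSE)
  labels <- paste0("n", seq_len(n))
  network(cbind(labels[el[, 1]], labels[el[, 2]]), nodes = labels)
}

#' Barabasi-Albert preferential-attachment network
#'
#' Grows from a clique on `m_attach + 1` nodes; each new node attaches to
#' `m_attach` distinct existing nodes chosen with probability proportional
#' to their current degree. The edge count is therefore exactly
#' `choose(m_attach + 1, 2) + (n - m_attach - 1) * m_attach`.
#'
#' @param n number of nodes
#' @param m_attach edges added per new node, `1 <= m_attach < n`
#' @param seed optional RNG seed
#' @return a [network()]
#' @export
barabasi_albert <- function(n, m_attach, seed = NULL) {
  if (m_attach < 1 || m_attach >= n)
    stop("require 1 <= m_attach < n")
  if (!is.null(seed)) set.seed(seed)
  m0 <- m_attach + 1
  seed_edges <- t(utils::combn(m0, 2))
  total <- nrow(seed_edges) + (n - m0) * m_attach
  from <- integer(total)
  to <- integer(total)
  from[seq_len(nrow(seed_edges))] <- seed_edges[, 1]
  to[seq_len(nrow(seed_edges))] <- seed_edges[, 2]
  deg <- integer(n)
  deg[1:m0] <- m_attach
  pos <- nrow(seed_edges)
  for (v in seq(m0 + 1, length.out = n - m0)) {
    tgt <- sample(v - 1L, m_attach, prob = deg[seq_len(v - 1)])
    from[pos + seq_len(m_attach)] <- v
    to[pos + seq_len(m_attach)] <- tgt
    deg[tgt] <- deg[tgt] + 1L
    deg[v] <- m_attach
    pos <- pos + m_attach
  }
  labels <- paste0("n", seq_len(n))
  network(cbind(labels[from], labels[to]), nodes = labels)
}

#' Planted-partition benchmark graph
#'
#' Equal-size modules; each within-module pair is linked independently
#' with probability `p_in`, each between-module pair with `p_out`. The
#' ground-truth partition is returned alongside the graph, which makes
#' this the standard fixture for module-recovery experiments.
#'
#' @param n_modules number of planted modules
#' @param module_size nodes per module
#' @param p_in,p_out within/between-module edge probabilities,
#'   `0 <= p_out <= p_in <= 1`
#' @param seed optional RNG seed
#' @return list with elements `network` and `partition` (ground truth,
#'   modules labelled `M1..M<n_modules>`)
#' @export
planted_partition <- function(n_modules, module_size, p_in, p_out,
                              seed = NULL) {
  stopifnot(n_modules >= 1, module_size >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= p_in)
  if (!is.null(seed)) set.seed(seed)
  n <- n_modules * module_size
  pm <- matrix(p_out, n_modules, n_modules)
  diag(pm) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pm,
                          block.sizes = rep(module_size, n_modules))
  labels <- paste0("n", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  net <- network(cbind(labels[el[, 1]], labels[el[, 2]]), nodes = labels)
  block <- rep(paste0("M", seq_len(n_modules)), each = module_size)
  list(network = net, partition = partition(setNames(block, labels)))
}
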