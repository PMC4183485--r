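# Fixtures and independent oracles, all built in code at test time.

clique_edges <- function(labels) {
  t(combn(labels, 2))
}

# Random simple graph with n nodes and m edges, drawn with the caller's
# RNG state (no internal seed), plus isolated-node coverage.
rand_network <- function(n, m = NULL) {
  if (is.null(m)) m <- sample.int(max(1, n * (n - 1) / 2), 1)
  pairs <- t(combn(n, 2))
  pick <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ,
                drop = FALSE]
  labels <- paste0("v", seq_len(n))
  network(cbind(labels[pick[, 1]], labels[pick[, 2]]), nodes = labels)
}

rand_partition <- function(net, k = NULL) {
  n <- n_nodes(net)
  if (is.null(k)) k <- sample(2:min(5, n), 1)
  partition(setNames(paste0("C", sample.int(k, n, replace = TRUE)),
                     net$nodes))
}

# Exhaustive k-means oracle: minimum SSE over every assignment of n
# points to at most k clusters, vectorized over the k^n assignments.
brute_sse <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  sse <- rep(sum(X^2), nrow(A))
  for (c in seq_len(k)) {
    Mc <- (A == c) * 1
    nc <- rowSums(Mc)
    for (d in seq_len(ncol(X))) {
      S2 <- (Mc %*% X[, d])^2
      S2[nc == 0] <- 0
      sse <- sse - S2 / pmax(nc, 1)
    }
  }
  min(sse)
}

# Reachability oracle for components: boolean matrix powers.
components_by_matrix_powers <- function(net) {
  A <- adjacency_matrix(net) > 0
  diag(A) <- TRUE
  for (i in seq_len(n_nodes(net))) {
    R <- (A %*% A) > 0
    if (all(R == A)) break
    A <- R
  }
  unique(apply(A, 1, function(r) paste(net$nodes[r], collapse = ",")))
}

# Minimal PDB ATOM writer for alpha-carbon fixtures.
pdb_atom_line <- function(serial, chain, resno, x, y, z,
                          alt = " ", icode = " ", resn = "ALA",
                          record = "ATOM  ", name = " CA ") {
  paste0(record, formatC(serial, width = 5), " ", name, alt,
         resn, " ", chain, formatC(resno, width = 4), icode, "   ",
         formatC(x, format = "f", digits = 3, width = 8),
         formatC(y, format = "f", digits = 3, width = 8),
         formatC(z, format = "f", digits = 3, width = 8),
         "  1.00  0.00           C")
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Same module sets regardless of labelling?
same_partition <- function(p, q) {
  isTRUE(all.equal(ari(module_index(p)[sort(p$nodes)],
                       module_index(q)[sort(q$nodes)]), 1))
}
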