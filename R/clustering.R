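# Partitioning engines: spectral clustering on Laplacian eigenvectors,
# k-means on graph metrics (shortest-path / Hamming embeddings), and the
# Markov Cluster algorithm. All engines consume the unweighted adjacency
# matrix and return total partitions.

#' Graph Laplacian
#'
#' Unnormalized: `L = D - A` with `D` the diagonal degree matrix.
#' Normalized: the random-walk form `L = I - D^-1 A`, with the row of any
#' degree-zero node replaced by the corresponding identity row.
#'
#' @param net a `carto_network`
#' @param mode `"unnormalized"` or `"normalized"`
#' @return square numeric matrix in node order
#' @export
graph_laplacian <- function(net, mode = c("unnormalized", "normalized")) {
  mode <- match.arg(mode)
  A <- adjacency_matrix(net)
  d <- rowSums(A)
  if (mode == "unnormalized") {
    L <- -A
    diag(L) <- d
  } else {
    P <- A / ifelse(d == 0, 1, d)   # divides row i by d[i]
    L <- -P
    diag(L) <- diag(L) + 1
  }
  L
}

# Deterministic sign convention: the first entry of each eigenvector whose
# magnitude exceeds tol is made positive, so repeated runs embed nodes
# identically.
fix_eigenvector_signs <- function(U, tol = 1e-8) {
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > tol)
    if (length(nz) && U[nz[1], j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Spectral partition of a network
#'
#' Embeds each node as its row in the matrix of eigenvectors belonging to
#' the `k` smallest Laplacian eigenvalues, then clusters the rows with
#' Euclidean k-means. The normalized mode uses the random-walk Laplacian.
#' Connectivity is not required; a graph with `c <= k` components has `c`
#' zero eigenvalues whose indicator eigenvectors separate the components
#' exactly.
#'
#' @param net a `carto_network`
#' @param k number of clusters, `2 <= k <= n`
#' @param mode Laplacian mode, see [graph_laplacian()]
#' @param restarts,max_iter,seed k-means controls, see [kmeans_partition()]
#' @return a [partition()] with at most `k` nonempty modules, labelled
#'   `M1..` in first-seen node order
#' @export
spectral_partition <- function(net, k,
                               mode = c("normalized", "unnormalized"),
                               restarts = 10, max_iter = 300, seed = NULL) {
  mode <- match.arg(mode)
  n <- n_nodes(net)
  if (k > n) stop("k > n")
  if (k < 2) stop("k must be at least 2")
  L <- graph_laplacian(net, mode)
  if (mode == "unnormalized") {
    e <- eigen(L, symmetric = TRUE)
    vals <- e$values
    vecs <- e$vectors
  } else {
    e <- eigen(L)                    # eigenvalues are real (similar to a
    vals <- Re(e$values)             # symmetric matrix); drop fp residue
    vecs <- Re(e$vectors)
  }
  ord <- order(vals)
  U <- fix_eigenvector_signs(vecs[, ord[seq_len(k)], drop = FALSE])
  fit <- kmeans_lloyd(U, k, max_iter = max_iter, restarts = restarts,
                      seed = seed)
  partition(setNames(paste0("M", match(fit$cluster, unique(fit$cluster))),
                     net$nodes))
}

#' Node-to-node distance matrix
#'
#' `shortest_path`: unweighted hop counts; pairs in different components
#' get the finite surrogate `n` (strictly larger than any true path), so
#' the k-means embedding stays well defined on disconnected graphs.
#' `hamming`: number of coordinates in which the two adjacency-matrix rows
#' differ, over all `n` coordinates.
#'
#' @param net a `carto_network`
#' @param metric `"shortest_path"` or `"hamming"`
#' @return symmetric numeric matrix with zero diagonal, node order rows
#' @export
distance_matrix <- function(net, metric = c("shortest_path", "hamming")) {
  metric <- match.arg(metric)
  n <- n_nodes(net)
  if (n == 0) stop("empty network")
  if (metric == "shortest_path") {
    d <- igraph::distances(as_igraph(net))
    d[is.infinite(d)] <- n
    d[net$nodes, net$nodes, drop = FALSE]
  } else {
    A <- adjacency_matrix(net)
    deg <- rowSums(A)
    outer(deg, deg, "+") - 2 * (A %*% A)
  }
}

# Squared Euclidean distances from each row of X to each row of C.
dist2_to_centers <- function(X, C) {
  D2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  D2[D2 < 0] <- 0                    # fp noise on coincident points
  D2
}

# k-means++ seeding: first center uniform, then each with probability
# proportional to the squared distance to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  C <- matrix(0, k, ncol(X))
  C[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- dist2_to_centers(X, C[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      idx <- if (sum(d2) > 0) sample.int(n, 1, prob = d2)
             else sample.int(n, 1)
      C[j, ] <- X[idx, ]
      d2 <- pmin(d2, dist2_to_centers(X, C[j, , drop = FALSE])[, 1])
    }
  }
  C
}

kmeans_once <- function(X, k, max_iter) {
  n <- nrow(X)
  C <- kmeanspp_init(X, k)
  prev <- integer(n)
  for (it in seq_len(max_iter)) {
    D2 <- dist2_to_centers(X, C)
    a <- max.col(-D2, ties.method = "first")
    guard <- 0
    repeat {                         # empty cluster: reseed with the point
      empty <- which(tabulate(a, k) == 0)   # farthest from its centroid
      if (!length(empty) || guard >= k) break
      far <- which.max(D2[cbind(seq_len(n), a)])
      C[empty[1], ] <- X[far, ]
      D2 <- dist2_to_centers(X, C)
      a <- max.col(-D2, ties.method = "first")
      guard <- guard + 1
    }
    for (j in seq_len(k)) {
      if (any(a == j)) C[j, ] <- colMeans(X[a == j, , drop = FALSE])
    }
    if (identical(a, prev)) break
    prev <- a
  }
  D2 <- dist2_to_centers(X, C)
  a <- max.col(-D2, ties.method = "first")
  list(cluster = a, sse = sum(D2[cbind(seq_len(n), a)]))
}

# Best of `restarts` Lloyd runs by SSE; RNG state is seeded once so the
# whole restart sequence is reproducible.
kmeans_lloyd <- function(X, k, max_iter = 300, restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- kmeans_once(X, k, max_iter)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}

#' k-means partition of a network or point set
#'
#' Lloyd iterations with the centroid as arithmetic mean, k-means++
#' initialization, and the best of `restarts` runs by SSE (sum of squared
#' distances of members to their centroid). For a network, each node is
#' embedded as its row of the [distance_matrix()] for the chosen graph
#' metric and clustered in that Euclidean space; a plain numeric matrix is
#' clustered directly (`metric = "euclidean"`). An empty cluster arising
#' during iteration is reseeded with the point farthest from its centroid.
#'
#' @param x a `carto_network` or a numeric matrix of points (rows)
#' @param k number of clusters, `1 <= k <=` number of points
#' @param metric `"shortest_path"`, `"hamming"` (network input) or
#'   `"euclidean"` (matrix input)
#' @param max_iter Lloyd iteration cap per restart
#' @param restarts independent k-means++ starts
#' @param seed optional RNG seed
#' @return list with elements `partition` (a [partition()]) and `sse`
#' @export
kmeans_partition <- function(x, k,
                             metric = c("shortest_path", "hamming",
                                        "euclidean"),
                             max_iter = 300, restarts = 10, seed = NULL) {
  metric <- match.arg(metric)
  if (inherits(x, "carto_network")) {
    if (metric == "euclidean")
      stop("network input requires the shortest_path or hamming metric")
    X <- distance_matrix(x, metric)
    labels <- x$nodes
  } else {
    X <- as.matrix(x)
    labels <- rownames(X)
    if (is.null(labels)) labels <- paste0("p", seq_len(nrow(X)))
  }
  if (k < 1) stop("k must be positive")
  if (k > nrow(X)) stop("k > n")
  fit <- kmeans_lloyd(X, k, max_iter = max_iter, restarts = restarts,
                      seed = seed)
  list(partition = partition(
         setNames(paste0("M", match(fit$cluster, unique(fit$cluster))),
                  labels)),
       sse = fit$sse)
}

#' SSE versus k curve for the elbow heuristic
#'
#' Runs [kmeans_partition()] for every `k` in `[k_min, k_max]` on the same
#' graph-metric embedding and reports the attained SSE. The curve is meant
#' to be inspected for its elbow — the k past which the SSE stops dropping
#' sharply; no automatic selection is performed.
#'
#' @param net a `carto_network`
#' @param metric graph metric, see [distance_matrix()]
#' @param k_min,k_max inclusive scan range, `1 <= k_min <= k_max <= n`
#' @param restarts k-means restarts per k
#' @param seed optional base seed; k-specific seeds are derived from it
#' @return data frame with columns `k` and `sse`, `k` strictly increasing
#' @export
sse_scan <- function(net, metric = c("shortest_path", "hamming"),
                     k_min = 1, k_max, restarts = 10, seed = NULL) {
  metric <- match.arg(metric)
  n <- n_nodes(net)
  stopifnot(k_min >= 1, k_min <= k_max, k_max <= n)
  X <- distance_matrix(net, metric)
  ks <- k_min:k_max
  sse <- vapply(ks, function(k) {
    kmeans_lloyd(X, k, restarts = restarts,
                 seed = if (is.null(seed)) NULL else seed + k)$sse
  }, numeric(1))
  data.frame(k = ks, sse = sse)
}

#' Markov Cluster (MCL) partition
#'
#' Simulates flow on the graph: the adjacency matrix plus unit self-loops
#' is column-normalized to a stochastic matrix, then expansion (matrix
#' squaring) alternates with inflation (elementwise power `inflation`,
#' entries below `prune_threshold` zeroed, columns renormalized) until the
#' matrix changes by less than `tol` or `max_iter` is reached. Clusters
#' are the connected components of the nonzero structure of the converged
#' matrix. Larger inflation yields more, smaller clusters.
#'
#' @param net a `carto_network`
#' @param inflation inflation exponent, must exceed 1 (default 2)
#' @param prune_threshold entries below this are zeroed each iteration
#' @param tol convergence threshold on the max absolute matrix change
#' @param max_iter iteration cap; on non-convergence the current partition
#'   is returned with a warning and `attr(, "converged") = FALSE`
#' @return a [partition()]; attribute `converged` records convergence
#' @export
mcl_partition <- function(net, inflation = 2, prune_threshold = 1e-10,
                          tol = 1e-6, max_iter = 200) {
  if (inflation <= 1) stop("inflation must exceed 1")
  A <- adjacency_matrix(net)
  diag(A) <- 1                       # self-loops stabilize the flow
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- M2^inflation               # inflation
    M2[M2 < prune_threshold] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  S <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(S * 1, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  p <- partition(setNames(paste0("M", match(memb, unique(memb))),
                          net$nodes))
  attr(p, "converged") <- converged
  p
}
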