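# Node role cartography: within-module z-score, participation coefficient
# (original Guimera-Amaral and a modified single-term variant), and the
# seven-region role classification in the (P, z) plane.

#' Per-node link counts towards each module
#'
#' @param net a `carto_network`
#' @param p a total [partition()] over the network's nodes
#' @return integer matrix, rows = nodes (node order), columns = modules
#'   (first-seen order); entry `[i, s]` is the number of links of node i
#'   into module s, so each row sums to the node's degree.
#' @export
module_link_counts <- function(net, p) {
  check_partition(net, p)
  mlab <- p$module_labels
  K <- matrix(0, n_nodes(net), length(mlab),
              dimnames = list(net$nodes, mlab))
  if (n_edges(net)) {
    u <- net$edges[, 1]
    v <- net$edges[, 2]
    K <- K +
      unclass(table(factor(u, levels = net$nodes),
                    factor(p$labels[v], levels = mlab))) +
      unclass(table(factor(v, levels = net$nodes),
                    factor(p$labels[u], levels = mlab)))
  }
  storage.mode(K) <- "integer"
  K
}

# kappa_i: links of each node into its own module.
own_module_links <- function(K, net, p) {
  K[cbind(seq_len(nrow(K)), match(p$labels[net$nodes], colnames(K)))]
}

#' Within-module z-score of intra-module degree
#'
#' Standardizes each node's intra-module link count kappa. In the default
#' `within_module` mode the mean and standard deviation are taken over the
#' nodes of the node's own module; in `global` mode over all nodes. The
#' population (divide-by-n) standard deviation is used, and a zero
#' standard deviation yields z = 0 by convention.
#'
#' @param net a `carto_network`
#' @param p a total [partition()]
#' @param mode `"within_module"` (default) or `"global"`
#' @return named numeric vector of z-scores in node order
#' @export
within_module_zscores <- function(net, p,
                                  mode = c("within_module", "global")) {
  mode <- match.arg(mode)
  K <- module_link_counts(net, p)
  kappa <- own_module_links(K, net, p)
  z <- numeric(length(kappa))
  if (mode == "global") {
    mu <- mean(kappa)
    s <- sqrt(mean((kappa - mu)^2))
    if (s > 0) z <- (kappa - mu) / s
  } else {
    labs <- p$labels[net$nodes]
    for (m in p$module_labels) {
      idx <- which(labs == m)
      mu <- mean(kappa[idx])
      s <- sqrt(mean((kappa[idx] - mu)^2))
      z[idx] <- if (s > 0) (kappa[idx] - mu) / s else 0
    }
  }
  setNames(z, net$nodes)
}

#' Participation coefficients
#'
#' The `original` Guimera-Amaral definition is
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` over all modules s; its maximum is
#' `1 - 1/N` (attained when the links spread uniformly over the N
#' modules), so it can never reach 1. The `modified` (default) variant
#' uses only the own-module term, `P_i = 1 - (kappa_i / k_i)^2`: it is
#' independent of the module count and attains 1, which lets strongly
#' inter-modular ("kinless") nodes stand out however few modules exist.
#' Isolated nodes (`k_i = 0`) get `P_i = 0` by convention.
#'
#' @param net a `carto_network`
#' @param p a total [partition()]
#' @param variant `"modified"` (default) or `"original"`
#' @return named numeric vector in `[0, 1]`, node order
#' @export
participation_coefficients <- function(net, p,
                                       variant = c("modified",
                                                   "original")) {
  variant <- match.arg(variant)
  K <- module_link_counts(net, p)
  k <- rowSums(K)
  kdiv <- pmax(k, 1)
  P <- if (variant == "modified") {
    1 - (own_module_links(K, net, p) / kdiv)^2
  } else {
    1 - rowSums((K / kdiv)^2)
  }
  P[k == 0] <- 0
  setNames(as.numeric(P), net$nodes)
}

#' Role-region thresholds
#'
#' Boundaries of the seven role regions in the (P, z) plane. Nodes with
#' `z >= z_hub` are module hubs. Non-hubs split on P at `p1 < p2 < p3`
#' into R1 (ultra-peripheral), R2 (peripheral), R3 (non-hub connector) and
#' R4 (non-hub kinless); hubs split at `p5 < p6` into R5 (provincial
#' hub), R6 (connector hub) and R7 (kinless hub). The default
#' `p3 = 0.8775 = 1 - 0.35^2` makes R4 membership under the modified
#' participation coefficient exactly "fewer than 35% of the node's links
#' inside its own module"; the remaining defaults follow the classical
#' cartography. An upper boundary belongs to the lower region.
#'
#' @param z_hub hub threshold on the z-score (default 2.5)
#' @param p1,p2,p3 non-hub P boundaries, `0 < p1 < p2 < p3 < 1`
#' @param p5,p6 hub P boundaries, `0 < p5 < p6 < 1`
#' @return object of class `region_thresholds`
#' @export
region_thresholds <- function(z_hub = 2.5, p1 = 0.05, p2 = 0.62,
                              p3 = 1 - 0.35^2, p5 = 0.30, p6 = 0.75) {
  stopifnot(0 < p1, p1 < p2, p2 < p3, p3 < 1, 0 < p5, p5 < p6, p6 < 1)
  structure(list(z_hub = z_hub, p1 = p1, p2 = p2, p3 = p3,
                 p5 = p5, p6 = p6),
            class = "region_thresholds")
}

#' @export
print.region_thresholds <- function(x, ...) {
  cat(sprintf(
    "<region thresholds: z_hub=%g; non-hub P cuts %g/%g/%g; hub P cuts %g/%g>\n",
    x$z_hub, x$p1, x$p2, x$p3, x$p5, x$p6))
  invisible(x)
}

#' Classify nodes into role regions R1-R7
#'
#' Total function on the strip `P in [0, 1]`, `z` real: every (z, P) pair
#' maps to exactly one region. A node is a hub iff `z >= z_hub`; within
#' each band the upper P boundary belongs to the lower region.
#'
#' @param z numeric vector of within-module z-scores
#' @param P numeric vector of participation coefficients in `[0, 1]`
#' @param thresholds a [region_thresholds()] object
#' @return character vector of `"R1"`..`"R7"`
#' @export
classify_node <- function(z, P, thresholds = region_thresholds()) {
  stopifnot(length(z) == length(P))
  if (any(P < 0 | P > 1)) stop("P outside [0, 1]")
  th <- thresholds
  hub <- z >= th$z_hub
  region <- character(length(z))
  nh <- P[!hub]
  region[!hub] <- ifelse(nh <= th$p1, "R1",
                  ifelse(nh <= th$p2, "R2",
                  ifelse(nh <= th$p3, "R3", "R4")))
  hb <- P[hub]
  region[hub] <- ifelse(hb <= th$p5, "R5",
                 ifelse(hb <= th$p6, "R6", "R7"))
  region
}

#' Full cartography table for a partitioned network
#'
#' One record per node, in node order: module, total degree `k`,
#' intra-module degree `kappa`, within-module z-score, participation
#' coefficient and role region under the active thresholds.
#'
#' @param net a `carto_network`
#' @param p a total [partition()]
#' @param thresholds a [region_thresholds()] object
#' @param zmode z-score mode, see [within_module_zscores()]
#' @param variant participation variant, see
#'   [participation_coefficients()]
#' @return data frame with columns `node`, `module`, `degree`, `kappa`,
#'   `z`, `P`, `region`
#' @export
build_cartography <- function(net, p, thresholds = region_thresholds(),
                              zmode = c("within_module", "global"),
                              variant = c("modified", "original")) {
  zmode <- match.arg(zmode)
  variant <- match.arg(variant)
  check_partition(net, p)
  K <- module_link_counts(net, p)
  z <- within_module_zscores(net, p, zmode)
  P <- participation_coefficients(net, p, variant)
  data.frame(node = net$nodes,
             module = unname(p$labels[net$nodes]),
             degree = as.integer(rowSums(K)),
             kappa = as.integer(own_module_links(K, net, p)),
             z = unname(z),
             P = unname(P),
             region = classify_node(unname(z), unname(P), thresholds),
             stringsAsFactors = FALSE, row.names = NULL)
}

region_palette <- c(R1 = "#ffffff", R2 = "#fdb863", R3 = "#80cdc1",
                    R4 = "#000000", R5 = "#fee0b6", R6 = "#d6604d",
                    R7 = "#7b3294")

#' P-z scatter of a cartography
#'
#' Draws the (P, z) plane portrait: one point per node, filled by role
#' region, with the configured region boundaries as reference lines. The
#' device is chosen from the file extension (png, svg or pdf; png
#' otherwise).
#'
#' @param records data frame from [build_cartography()]
#' @param path output image path
#' @param thresholds a [region_thresholds()] object (used for the
#'   boundary lines; should match the one used to build `records`)
#' @return `path`, invisibly
#' @export
pz_scatter <- function(records, path, thresholds = region_thresholds()) {
  if (!NROW(records)) stop("no records to plot")
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         svg = grDevices::svg(path, width = 7, height = 5.5),
         pdf = grDevices::pdf(path, width = 7, height = 5.5),
         grDevices::png(path, width = 900, height = 700, res = 120))
  on.exit(grDevices::dev.off())
  th <- thresholds
  ylim <- range(c(records$z, th$z_hub, 3))
  ylim <- ylim + c(-0.3, 0.3) * diff(ylim)
  plot(records$P, records$z, xlim = c(0, 1), ylim = ylim,
       pch = 21, bg = region_palette[records$region], col = "grey30",
       xlab = "participation coefficient P",
       ylab = "within-module z-score", las = 1)
  usr <- par("usr")
  abline(h = th$z_hub, lty = 2, col = "grey40")
  segments(x0 = c(th$p1, th$p2, th$p3), y0 = usr[3], y1 = th$z_hub,
           lty = 3, col = "grey40")
  segments(x0 = c(th$p5, th$p6), y0 = th$z_hub, y1 = usr[4],
           lty = 3, col = "grey40")
  legend("topleft", legend = names(region_palette),
         pt.bg = region_palette, pch = 21, ncol = 4, bty = "n",
         cex = 0.75)
  invisible(path)
}
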