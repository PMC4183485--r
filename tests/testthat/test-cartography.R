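# Star-within-module fixture: one centre wired to m1 nodes of its own
# module and to nodes spread over other modules.
star_module_net <- function() {
  edges <- rbind(cbind("hub", paste0("a", 1:4)),
                 clique_edges(paste0("a", 1:4)))
  network(edges)
}

test_that("module link counts split degrees by neighbour module", {
  net <- network(rbind(c("x", "a1"), c("x", "a2"), c("x", "b1")))
  p <- partition(c(x = "A", a1 = "A", a2 = "A", b1 = "B"))
  K <- module_link_counts(net, p)
  expect_equal(K["x", ], c(A = 2L, B = 1L))
  expect_equal(rowSums(K), degrees(net)[rownames(K)])

  iso <- network(rbind(c("a", "b")), nodes = "z")
  Ki <- module_link_counts(iso, partition(c(z = "1", a = "1", b = "2")))
  expect_equal(sum(Ki["z", ]), 0L)

  kl <- network(clique_edges(paste0("k", 1:5)))
  Kk <- module_link_counts(kl, partition(setNames(rep("m", 5), kl$nodes)))
  expect_true(all(Kk == 4L))

  expect_error(module_link_counts(net, partition(c(x = "A"))),
               "missing node")
})

test_that("within-module z-scores standardize kappa per module", {
  # star of 4 leaves inside one module: centre kappa 4, leaves kappa 1;
  # population mean 1.6, sd 1.2 -> z = 2.0 and -0.5
  net <- network(cbind("hub", paste0("a", 1:4)))
  p <- partition(setNames(rep("M", 5), net$nodes))
  z <- within_module_zscores(net, p)
  expect_equal(z[["hub"]], 2.0)
  expect_equal(unname(z[paste0("a", 1:4)]), rep(-0.5, 4))

  # identical-kappa module: sd = 0 convention gives z = 0
  cl <- network(clique_edges(c("p", "q", "r")))
  zc <- within_module_zscores(cl, partition(c(p = "1", q = "1", r = "1")))
  expect_equal(unname(zc), rep(0, 3))

  # standardization identity on random partitioned graphs
  set.seed(14)
  for (i in 1:10) {
    netr <- rand_network(12, 20)
    pr <- rand_partition(netr)
    zr <- within_module_zscores(netr, pr)
    for (nodes in modules(pr)) {
      expect_lt(abs(mean(zr[nodes])), 1e-12)
      s <- sqrt(mean((zr[nodes] - mean(zr[nodes]))^2))
      expect_true(abs(s) < 1e-12 || abs(s - 1) < 1e-9)
    }
  }
})

test_that("participation coefficients match both definitions", {
  # all links inside the own module
  cl <- network(clique_edges(paste0("c", 1:4)))
  pcl <- partition(setNames(rep("m", 4), cl$nodes))
  expect_equal(unname(participation_coefficients(cl, pcl, "modified")),
               rep(0, 4))
  expect_equal(unname(participation_coefficients(cl, pcl, "original")),
               rep(0, 4))

  # degree-4 node with one link into each of 4 modules: the original
  # definition caps at 1 - 1/N = 0.75, the modified reaches 0.9375
  net <- network(cbind("x", c("a", "b", "c", "d")))
  p <- partition(c(x = "A", a = "A", b = "B", c = "C", d = "D"))
  expect_equal(participation_coefficients(net, p, "original")[["x"]], 0.75)
  expect_equal(participation_coefficients(net, p, "modified")[["x"]],
               1 - (1 / 4)^2)

  # kappa/k = 0.35 sits exactly on the default R3/R4 boundary
  edges <- rbind(cbind("h", paste0("in", 1:7)),
                 cbind("h", paste0("out", 1:13)))
  ph <- partition(setNames(
    c("A", rep("A", 7), rep(c("B", "C", "D"), length.out = 13)),
    c("h", paste0("in", 1:7), paste0("out", 1:13))))
  Ph <- participation_coefficients(network(edges), ph, "modified")[["h"]]
  expect_equal(Ph, 1 - 0.35^2)
  expect_equal(Ph, 0.8775)

  # isolated node: P = 0 by convention
  iso <- network(rbind(c("a", "b")), nodes = "z")
  expect_equal(participation_coefficients(
    iso, partition(c(z = "1", a = "1", b = "1")))[["z"]], 0)
})

test_that("role regions partition the (z, P) strip", {
  th <- region_thresholds()
  expect_equal(classify_node(0, 0, th), "R1")
  expect_equal(classify_node(3, 0, th), "R5")
  expect_equal(classify_node(2.5, 0, th), "R5")   # z = z_hub is a hub
  expect_equal(classify_node(0, 0.05, th), "R1")  # upper bound -> lower region
  expect_equal(classify_node(0, 0.8775, th), "R3")
  expect_equal(classify_node(0, 0.91, th), "R4")  # intra fraction 0.30
  expect_equal(classify_node(3, 0.8, th), "R7")

  grid <- expand.grid(z = seq(-5, 5, length.out = 100),
                      P = seq(0, 1, length.out = 100))
  regions <- classify_node(grid$z, grid$P, th)
  expect_true(all(regions %in% paste0("R", 1:7)))
  expect_length(regions, nrow(grid))

  expect_error(classify_node(0, 1.2, th), "outside")
  expect_error(region_thresholds(p2 = 0.9), "p2 < p3")
})

test_that("cartography tables combine the descriptors coherently", {
  # two disjoint 4-cliques with their natural partition: regular modules,
  # no inter-module links -> everything R1 at the origin
  net <- network(rbind(clique_edges(paste0("a", 1:4)),
                       clique_edges(paste0("b", 1:4))))
  p <- partition(setNames(rep(c("A", "B"), each = 4), net$nodes))
  rec <- build_cartography(net, p)
  expect_equal(nrow(rec), 8)
  expect_true(all(rec$z == 0))
  expect_true(all(rec$P == 0))
  expect_true(all(rec$region == "R1"))

  # a bridge node holding under 35% of its links in its own module is R4
  edges <- rbind(clique_edges(paste0("m1_", 1:5)),
                 clique_edges(paste0("m2_", 1:5)),
                 clique_edges(paste0("m3_", 1:5)),
                 cbind("bridge", c("m1_1", paste0("m2_", 1:2),
                                   paste0("m3_", 1:2))))
  net2 <- network(edges)
  p2 <- partition(setNames(
    c(rep("M1", 5), rep("M2", 5), rep("M3", 5), "M1"),
    c(paste0("m1_", 1:5), paste0("m2_", 1:5), paste0("m3_", 1:5),
      "bridge")))
  rec2 <- build_cartography(net2, p2)
  b <- rec2[rec2$node == "bridge", ]
  expect_equal(b$kappa / b$degree, 0.2)
  expect_lt(b$z, 2.5)
  expect_equal(b$region, "R4")

  # conservation and record count on random instances
  set.seed(3)
  for (i in 1:5) {
    netr <- rand_network(10, 15)
    pr <- rand_partition(netr)
    recr <- build_cartography(netr, pr)
    expect_equal(nrow(recr), n_nodes(netr))
    expect_equal(recr$degree, unname(degrees(netr)))
    expect_equal(rowSums(module_link_counts(netr, pr)),
                 setNames(recr$degree, recr$node))
  }
})

test_that("descriptors are invariant under module relabelling", {
  set.seed(8)
  net <- rand_network(12, 22)
  p <- rand_partition(net, 3)
  perm <- c(C1 = "zebra", C2 = "apple", C3 = "mango")
  q <- partition(setNames(perm[p$labels], p$nodes))
  for (variant in c("modified", "original")) {
    expect_equal(participation_coefficients(net, p, variant),
                 participation_coefficients(net, q, variant))
  }
  expect_equal(within_module_zscores(net, p),
               within_module_zscores(net, q))
  expect_equal(build_cartography(net, p)$region,
               build_cartography(net, q)$region)
})

test_that("P-z scatter writes a non-empty image with any region mix", {
  net <- network(rbind(clique_edges(paste0("a", 1:4)),
                       clique_edges(paste0("b", 1:4))))
  p <- partition(setNames(rep(c("A", "B"), each = 4), net$nodes))
  rec <- build_cartography(net, p)
  for (ext in c(".png", ".pdf", ".svg")) {
    path <- tempfile(fileext = ext)
    pz_scatter(rec, path)
    expect_true(file.exists(path))
    expect_gt(file.info(path)$size, 0)
  }
  expect_error(pz_scatter(rec[0, ], tempfile(fileext = ".png")),
               "no records")
})
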