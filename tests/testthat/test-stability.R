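test_that("natural connectivity matches closed forms", {
  # edgeless: all eigenvalues 0 -> ln(N/N) = 0
  expect_equal(natural_connectivity(igraph::make_empty_graph(7,
                                                             directed = FALSE)),
               0)
  # K4: eigenvalues 3 and -1 (x3)
  expect_equal(natural_connectivity(igraph::make_full_graph(4)),
               log((exp(3) + 3 * exp(-1)) / 4), tolerance = 1e-12)
  expect_equal(natural_connectivity(igraph::make_full_graph(4)), 1.66720,
               tolerance = 1e-4)
  # P3: eigenvalues sqrt(2), 0, -sqrt(2)
  p3 <- igraph::make_graph(c(1,2, 2,3), directed = FALSE)
  expect_equal(natural_connectivity(p3),
               log((exp(sqrt(2)) + 1 + exp(-sqrt(2))) / 3), tolerance = 1e-12)
  expect_equal(natural_connectivity(p3), 0.5797, tolerance = 1e-4)
  # complete graphs up to N = 50, overflow-safe, 1e-9 tolerance
  for (n in c(2, 10, 25, 50))
    expect_equal(natural_connectivity(igraph::make_full_graph(n)),
                 nc_complete(n), tolerance = 1e-9)
})

test_that("natural connectivity never increases under edge deletion", {
  set.seed(19)
  for (rep_i in 1:8) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnm(n, sample.int(n * (n - 1) / 2, 1))
    base <- natural_connectivity(g)
    for (e in seq_len(igraph::gsize(g)))
      expect_lte(natural_connectivity(igraph::delete_edges(g, e)),
                 base + 1e-12)
  }
})

test_that("robustness_curve fits the decay of the averaged curve", {
  # edgeless graph: identically zero curve, slope 0
  flat <- robustness_curve(igraph::make_empty_graph(10, directed = FALSE),
                           n_replicates = 5, seed = 1)
  expect_equal(attr(flat, "slope"), 0)
  expect_true(all(flat$mean_nc == 0))

  # K10 degrades faster than the star S10 (Monte-Carlo oracle ordering);
  # K_k remains after any removal from K10, so its curve is deterministic
  k10 <- robustness_curve(igraph::make_full_graph(10), n_replicates = 20,
                          seed = 2)
  s10 <- robustness_curve(igraph::make_star(10, mode = "undirected"),
                          n_replicates = 200, seed = 2)
  expect_gt(abs(attr(k10, "slope")), abs(attr(s10, "slope")))
  expect_equal(k10$mean_nc[1], nc_complete(10), tolerance = 1e-9)
  expect_equal(k10$mean_nc[6], nc_complete(5), tolerance = 1e-9)
  expect_true(all(k10$sd_nc < 1e-12))  # deterministic decay for K10

  # seeded reproducibility
  set.seed(99)
  g <- igraph::sample_gnm(12, 20)
  r1 <- robustness_curve(g, n_replicates = 10, seed = 5)
  r2 <- robustness_curve(g, n_replicates = 10, seed = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r2))

  # normalized curve starts at 1 and rescales the slope by nc(0)
  rn <- robustness_curve(g, n_replicates = 10, seed = 5, normalize = TRUE)
  expect_equal(rn$mean_nc[1], 1)
  expect_equal(attr(rn, "slope"),
               attr(r1, "slope") / r1$mean_nc[1], tolerance = 1e-9)
})

test_that("remove_kingdom deletes nodes with exact edge conservation", {
  g <- make_labeled_graph(c(A = 6, B = 5, C = 4),
                          within_edges = list(A = 5, B = 4, C = 3),
                          cross_edges = data.frame(
                            kingdom_a = c("A", "A", "B"),
                            kingdom_b = c("B", "C", "C"),
                            edges = c(4, 3, 2)), seed = 23)
  igraph::E(g)$sign <- rep(c(1, -1), length.out = igraph::gsize(g))
  net <- signed_network(g)
  cut <- remove_kingdom(net, "B")
  expect_false("B" %in% igraph::V(cut$graph)$kingdom)
  incident_to_b <- sum(igraph::degree(
    g, igraph::V(g)[igraph::V(g)$kingdom == "B"])) -
    4  # within-B edges counted twice in the degree sum
  expect_equal(igraph::gsize(g),
               igraph::gsize(cut$graph) + incident_to_b)
  # removing a kingdom with no nodes is the identity
  none <- remove_kingdom(net, "D")
  expect_equal(igraph::gsize(none$graph), igraph::gsize(g))
  # cannot remove everything
  mono <- signed_network(make_labeled_graph(c(A = 4, B = 2),
                                            within_edges = list(A = 2, B = 1),
                                            seed = 1))
  expect_error(remove_kingdom(remove_kingdom(mono, "B"), "A"), "every node")
})

test_that("removing an articulation kingdom lowers natural connectivity", {
  # planted topology: kingdom B bridges two otherwise separate cliques
  g <- igraph::make_graph(c(1,2, 1,3, 2,3,   4,5, 4,6, 5,6,
                            7,1, 7,4, 7,2, 7,5), directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:7)
  igraph::V(g)$kingdom <- c(rep("A", 3), rep("C", 3), "B")
  net <- signed_network(g)
  expect_lt(natural_connectivity(remove_kingdom(net, "B")),
            natural_connectivity(net))
})

test_that("add_kingdom induce mode partitions the induced subgraph exactly", {
  g <- make_labeled_graph(c(A = 6, B = 6, C = 5),
                          within_edges = list(A = 6, B = 5, C = 4),
                          cross_edges = data.frame(
                            kingdom_a = c("A", "A", "B"),
                            kingdom_b = c("B", "C", "C"),
                            edges = c(5, 4, 3)), seed = 31)
  igraph::E(g)$sign <- 1
  net <- signed_network(g)
  exp_ab <- add_kingdom(base = "A", added = "B", mode = "induce",
                        multi_net = net, stability = FALSE)
  dec <- decompose_links(exp_ab$net)
  expect_equal(sum(dec$edges), 6 + 5 + 5)  # A-within + B-within + A-B cross
  expect_equal(attr(dec, "cross_total"), 5)
  expect_equal(exp_ab$base_topology$edge_count, 6)
  expect_error(add_kingdom(base = "A", added = "Z", mode = "induce",
                           multi_net = net), "unknown kingdom")
})

test_that("reinfer-mode kingdom addition behaves as the simulation oracle predicts", {
  # two kingdoms with NO true cross-associations: adding B leaves A's
  # within-edges essentially unchanged and adds almost no cross edges
  spec0 <- precision_spec(c(A = 15, B = 15), topology = "band",
                          cross_kingdom_density = 0, seed = 41)
  ds0 <- make_synthetic_dataset(spec0, n_samples = 150, mean_depth = 2000,
                                seed = 41)
  exp0 <- add_kingdom(ds0$counts$A, ds0$counts$B, mode = "reinfer",
                      stability = FALSE, n_subsamples = 15, seed = 9)
  within_a <- function(net) {
    el <- igraph::as_edgelist(net$graph)
    keep <- grepl("^A", el[, 1]) & grepl("^A", el[, 2])
    edge_key(el[keep, 1], el[keep, 2])
  }
  base_edges <- within_a(exp0$base_net)
  aug_edges <- within_a(exp0$net)
  overlap <- length(intersect(base_edges, aug_edges)) /
    max(length(union(base_edges, aug_edges)), 1)
  expect_gt(overlap, 0.6)  # oracle run: 0.69
  el_aug <- igraph::as_edgelist(exp0$net$graph)
  cross <- sum(xor(grepl("^A", el_aug[, 1]), grepl("^A", el_aug[, 2])))
  expect_lt(cross / (15 * 15), 0.05)  # oracle run: 3 of 225 possible

  # a fragile base plus a densely cross-linked added block: proportional
  # decay slows down (normalized slopes; oracle run -1.51 -> -1.07)
  spec1 <- precision_spec(c(A = 15, B = 15), topology = "random",
                          within_kingdom_density = 0.08,
                          cross_kingdom_density = 0.35, seed = 43)
  ds1 <- make_synthetic_dataset(spec1, n_samples = 150, mean_depth = 2000,
                                seed = 43)
  exp1 <- add_kingdom(ds1$counts$A, ds1$counts$B, mode = "reinfer",
                      stability = TRUE, n_replicates = 30,
                      n_subsamples = 15, seed = 9)
  expect_true(attr(exp1$curve, "normalized"))
  expect_lt(abs(attr(exp1$curve, "slope")),
            abs(attr(exp1$base_curve, "slope")))
})
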