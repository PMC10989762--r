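test_that("decompose_links books every edge into one kingdom pair", {
  g <- make_labeled_graph(c(A = 5, B = 5),
                          within_edges = list(A = 2, B = 1),
                          cross_edges = data.frame(kingdom_a = "A",
                                                   kingdom_b = "B",
                                                   edges = 3), seed = 2)
  igraph::E(g)$sign <- c(rep(1, 4), rep(-1, 2))
  dec <- decompose_links(signed_network(g))
  expect_equal(attr(dec, "within_total"), 3)
  expect_equal(attr(dec, "cross_total"), 3)
  expect_equal(sum(dec$edges), igraph::gsize(g))
  expect_equal(dec$positive + dec$negative, dec$edges)

  # totals identity on random labelled graphs
  set.seed(14)
  for (i in 1:5) {
    gg <- igraph::sample_gnm(20, 40)
    igraph::V(gg)$kingdom <- sample(c("f", "b", "a"), 20, replace = TRUE)
    igraph::E(gg)$sign <- sample(c(-1, 1), 40, replace = TRUE)
    d <- decompose_links(gg)
    expect_equal(attr(d, "within_total") + attr(d, "cross_total"), 40)
  }

  # single kingdom: no cross links
  g1 <- igraph::sample_gnm(6, 5)
  igraph::V(g1)$kingdom <- "fungi"
  expect_equal(attr(decompose_links(g1), "cross_total"), 0)

  gg <- igraph::sample_gnm(4, 3)
  igraph::V(gg)$kingdom <- c("a", NA, "b", "b")
  expect_error(decompose_links(gg), "kingdom label")
})

test_that("expected link proportions follow node shares", {
  # the timberline census: plants 102, nematodes 34, bacteria 1160,
  # archaea 76 around focal fungi
  counts <- c(plants = 102, nematodes = 34, fungi = 178, bacteria = 1160,
              archaea = 76)
  p <- expected_link_proportions(counts, focal = "fungi")
  expect_equal(sum(p), 1)
  expect_equal(round(100 * p, 1),
               c(plants = 7.4, nematodes = 2.5, bacteria = 84.5,
                 archaea = 5.5))
  # one non-focal kingdom gets everything
  expect_equal(unname(expected_link_proportions(c(a = 5, b = 9), "a")), 1)
  # symmetry
  expect_equal(unname(expected_link_proportions(
    c(a = 7, b = 7, c = 7, d = 7, e = 7), "a")), rep(0.25, 4))
  expect_error(expected_link_proportions(c(a = 1, b = 1), "z"), "focal")
})

test_that("preference deviates subtract matched keys and sum to zero", {
  obs <- c(plants = 13.8, nematodes = 4.5, bacteria = 72.7, archaea = 9.0)
  exp_ <- c(plants = 7.4, nematodes = 2.5, bacteria = 84.5, archaea = 5.5)
  dev <- preference_deviates(obs, exp_)
  expect_equal(unname(dev["plants"]), 6.4)
  # the published percentages themselves sum to 100.0 vs 99.9, so the
  # deviates sum to 0 only up to that printed rounding
  expect_lte(abs(sum(dev)), 0.11)
  expect_equal(preference_deviates(exp_, exp_),
               setNames(rep(0, 4), names(exp_)))
  # order-insensitive matching; mismatched keys rejected
  expect_equal(preference_deviates(obs, exp_[c(3, 1, 4, 2)]), dev)
  expect_error(preference_deviates(obs, c(exp_[-1], weird = 1)),
               "mismatched")
})

test_that("ER null ensemble preserves n, m and the sign multiset", {
  g <- make_labeled_graph(c(f = 6, b = 6),
                          within_edges = list(f = 4, b = 4),
                          cross_edges = data.frame(kingdom_a = "f",
                                                   kingdom_b = "b",
                                                   edges = 6), seed = 8)
  igraph::E(g)$sign <- rep(c(-1, 1), 7)
  net <- signed_network(g)
  res <- er_null_negative_proportion(
    net, group_a = function(v) v$kingdom == "f",
    group_b = function(v) v$kingdom == "b", n_random = 99, seed = 3)
  expect_s3_class(res, "null_ensemble_result")
  expect_false(res$degenerate)
  expect_true(is.finite(res$z))
  # the ensemble mean of the negative proportion matches the global
  # proportion (sign multiset is fixed and edges land uniformly)
  expect_equal(res$ensemble_mean, 0.5, tolerance = 0.05)
  # seeded determinism
  res2 <- er_null_negative_proportion(
    net, function(v) v$kingdom == "f", function(v) v$kingdom == "b",
    n_random = 99, seed = 3)
  expect_identical(res$z, res2$z)

  # every replicate graph has exactly m edges (checked via igraph directly)
  ms <- withr::with_seed(4, replicate(50, igraph::gsize(
    igraph::sample_gnm(12, 14))))
  expect_true(all(ms == 14))

  # all-negative signs: every replicate statistic is 1 -> sd 0, flagged
  igraph::E(g)$sign <- -1
  res0 <- er_null_negative_proportion(
    signed_network(g), function(v) v$kingdom == "f",
    function(v) v$kingdom == "b", n_random = 19, seed = 1)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$z))
  expect_equal(res0$observed, res0$ensemble_mean)  # numerator is 0 too

  expect_error(er_null_negative_proportion(
    net, function(v) v$kingdom == "x", function(v) v$kingdom == "b"),
    "non-empty")
})

test_that("small-graph ensemble mean matches the exhaustive enumeration oracle", {
  # 8 nodes, 10 edges, groups = first 4 vs last 4 nodes. Under G(n, m) with
  # a uniformly permuted sign multiset every (edge set, sign assignment) is
  # exchangeable, so E[negative proportion among cross edges | >=1 cross
  # edge] equals the global negative proportion; enumerate it by brute force
  # over sign placements on a fixed small edge set to confirm.
  set.seed(6)
  g <- igraph::sample_gnm(8, 10)
  igraph::V(g)$kingdom <- rep(c("u", "v"), each = 4)
  signs <- c(rep(-1, 4), rep(1, 6))
  igraph::E(g)$sign <- signs
  in_u <- rep(c(TRUE, FALSE), each = 4)
  el <- igraph::as_edgelist(g, names = FALSE)
  qual <- xor(in_u[el[, 1]], in_u[el[, 2]])
  # brute-force oracle: all C(10, 4) placements of the negative signs
  combos <- combn(10, 4)
  vals <- apply(combos, 2, function(neg) {
    s <- rep(1, 10); s[neg] <- -1
    mean(s[qual] < 0)
  })
  oracle_mean <- mean(vals)
  expect_equal(oracle_mean, 0.4, tolerance = 1e-12)  # = global proportion
  res <- er_null_negative_proportion(
    g, function(v) v$kingdom == "u", function(v) v$kingdom == "v",
    n_random = 499, seed = 9)
  expect_equal(res$ensemble_mean, oracle_mean, tolerance = 0.05)
  # observed equal to the ensemble mean would give Z = 0 (formula check)
  expect_equal(kingdomnet:::z_score(res$ensemble_mean, res$ensemble_mean,
                                    res$ensemble_sd), 0)
})
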