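#' Network-level topology summary
#'
#' Computes the descriptors used to compare single- and multi-kingdom
#' networks: node and edge counts, mean connectivity (2E/N), modularity of a
#' seeded Louvain partition on the unsigned unweighted graph, average
#' shortest-path length over reachable pairs, and the positive/negative edge
#' proportions. An edgeless graph reports 0 for modularity and path length.
#'
#' @param net A `signed_network` or igraph graph.
#' @param seed Seed for the Louvain community detection.
#' @return List of class `topology_summary` with fields `node_count`,
#'   `edge_count`, `mean_connectivity`, `modularity`,
#'   `average_path_length`, `positive_edge_proportion`,
#'   `negative_edge_proportion`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' topology_summary(g)$mean_connectivity  # 2*6/4 = 3
#' @export
topology_summary <- function(net, seed = 1L) {
  g <- as_sn_graph(net)
  n <- igraph::gorder(g)
  m <- igraph::gsize(g)
  if (n < 1) stop2("network must have at least one node")
  s <- igraph::edge_attr(g, "sign")
  gu <- unsigned_graph(g)
  mod <- if (m > 0) {
    with_seed(seed, igraph::modularity(igraph::cluster_louvain(gu)))
  } else 0
  apl <- if (m > 0) igraph::mean_distance(gu, directed = FALSE,
                                          unconnected = TRUE) else 0
  structure(
    list(node_count = n,
         edge_count = m,
         mean_connectivity = 2 * m / n,
         modularity = mod,
         average_path_length = apl,
         positive_edge_proportion = if (m > 0) mean(s > 0) else NA_real_,
         negative_edge_proportion = if (m > 0) mean(s < 0) else NA_real_),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<topology_summary> N=%d E=%d mean connectivity=%.1f ",
           "modularity=%.3f path length=%.2f neg=%.1f%%\n"),
    x$node_count, x$edge_count, x$mean_connectivity, x$modularity,
    x$average_path_length, 100 * (x$negative_edge_proportion %||% 0)))
  invisible(x)
}

# Strip edge weights so igraph treats the graph as unweighted.
unsigned_graph <- function(g) {
  if (!is.null(igraph::edge_attr(g, "weight")))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Node-level centralities
#'
#' Degree (all incident edges regardless of sign), normalized degree
#' `degree / (N - 1)`, and betweenness normalized by `(N-1)(N-2)/2`, with
#' log10 variants for display (zeros give `NA` in the log columns).
#'
#' @param net A `signed_network` or igraph graph.
#' @return Data frame with one row per node: `node`, `kingdom`, `guild`,
#'   `degree`, `normalized_degree`, `betweenness`,
#'   `log10_normalized_degree`, `log10_betweenness`.
#' @export
node_centralities <- function(net) {
  g <- as_sn_graph(net)
  n <- igraph::gorder(g)
  deg <- igraph::degree(g)
  nd <- if (n > 1) deg / (n - 1) else rep(0, n)
  btw <- igraph::betweenness(unsigned_graph(g), directed = FALSE,
                             normalized = n > 2)
  safe_log10 <- function(x) ifelse(x > 0, log10(x), NA_real_)
  data.frame(
    node = igraph::V(g)$name %||% as.character(seq_len(n)),
    kingdom = igraph::vertex_attr(g, "kingdom") %||% NA_character_,
    guild = igraph::vertex_attr(g, "guild") %||% NA_character_,
    degree = as.integer(deg),
    normalized_degree = nd,
    betweenness = btw,
    log10_normalized_degree = safe_log10(nd),
    log10_betweenness = safe_log10(btw),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of a centrality across kingdoms
#'
#' Kruskal-Wallis rank test followed by pairwise multiple comparison of mean
#' ranks (the Siegel-Castellan procedure implemented by `kruskalmc`-style
#' functions): the difference of mean ranks between two groups is declared
#' significant when it exceeds
#' `qnorm(1 - alpha / (k (k - 1))) * sqrt(N (N + 1) / 12 * (1/n_i + 1/n_j))`.
#' Rank tests are invariant to monotone transforms, so ranking the raw
#' values is equivalent to ranking their log10 transforms.
#'
#' @param values Numeric vector (e.g. normalized degree per node).
#' @param groups Factor or character vector of kingdom labels.
#' @param alpha Familywise significance level (default 0.05).
#' @return List of class `kingdom_comparison`: `statistic`, `p_value`,
#'   `pairwise` (data.frame `group_a`, `group_b`, `mean_rank_diff`,
#'   `critical`, `significant`).
#' @export
compare_centrality_by_kingdom <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop2("need at least 2 kingdoms")
  groups <- droplevels(groups)
  kw <- stats::kruskal.test(values, groups)
  rk <- rank(values)  # midranks for ties
  n_tot <- length(values)
  mr <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lev <- levels(groups)
  k <- length(lev)
  pairs <- utils::combn(lev, 2)
  crit_z <- stats::qnorm(1 - alpha / (k * (k - 1)))
  pw <- do.call(rbind, apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- abs(mr[[i]] - mr[[j]])
    crit <- crit_z * sqrt(n_tot * (n_tot + 1) / 12 *
                            (1 / ns[[i]] + 1 / ns[[j]]))
    data.frame(group_a = i, group_b = j, mean_rank_diff = diff,
               critical = crit, significant = diff > crit,
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = unname(kw$statistic),
                 p_value = kw$p.value, pairwise = pw, alpha = alpha),
            class = "kingdom_comparison")
}

#' @export
print.kingdom_comparison <- function(x, ...) {
  cat(sprintf("<kingdom_comparison> Kruskal-Wallis chi2=%.3f, p=%.4g\n",
              x$statistic, x$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
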