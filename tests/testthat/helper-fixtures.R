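# Shared fixtures and oracles, all built in code.

# Canonical unordered edge key for comparing edge sets.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# F1 of a predicted edge set against a truth edge set (keys).
edge_f1 <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  if (tp == 0) return(0)
  precision <- tp / length(pred)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}

# A labelled igraph with exact per-kingdom-pair edge counts, drawn uniformly
# (G(n, m) within blocks, bipartite G(n1, n2, m) across blocks).
make_labeled_graph <- function(node_counts, within_edges = NULL,
                               cross_edges = NULL, seed = 1) {
  withr::with_seed(seed, {
    offsets <- c(0, cumsum(node_counts))[seq_along(node_counts)]
    names(offsets) <- names(node_counts)
    el <- matrix(numeric(), 0, 2)
    for (k in names(within_edges %||% c())) {
      m <- within_edges[[k]]
      if (m == 0) next
      sub <- igraph::as_edgelist(igraph::sample_gnm(node_counts[[k]], m))
      el <- rbind(el, sub + offsets[[k]])
    }
    if (!is.null(cross_edges)) {
      for (i in seq_len(nrow(cross_edges))) {
        k1 <- cross_edges$kingdom_a[i]; k2 <- cross_edges$kingdom_b[i]
        m <- cross_edges$edges[i]
        if (m == 0) next
        gb <- igraph::sample_bipartite(node_counts[[k1]], node_counts[[k2]],
                                       type = "gnm", m = m)
        sub <- igraph::as_edgelist(gb)
        sub[, 1] <- sub[, 1] + offsets[[k1]]
        sub[, 2] <- sub[, 2] - node_counts[[k1]] + offsets[[k2]]
        el <- rbind(el, sub)
      }
    }
    g <- igraph::make_empty_graph(sum(node_counts), directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    igraph::V(g)$name <- paste0(rep(names(node_counts), node_counts), "_",
                                unlist(lapply(node_counts, seq_len)))
    igraph::V(g)$kingdom <- rep(names(node_counts), node_counts)
    g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Toy signed network: two kingdoms, explicit edges and signs.
toy_signed_network <- function() {
  g <- igraph::make_graph(~ a1 - a2, a2 - a3, a1 - b1, a2 - b1, b1 - b2,
                          b2 - a3)
  igraph::V(g)$kingdom <- c("A", "A", "A", "B", "B")[match(
    igraph::V(g)$name, c("a1", "a2", "a3", "b1", "b2"))]
  igraph::E(g)$sign <- c(1, -1, 1, 1, -1, 1)
  igraph::E(g)$weight <- abs(stats::rnorm(6))
  signed_network(g)
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); brute-force oracle for modularity.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(max_used + 1L))
      recurse(c(prefix, v), max(max_used, v))
  }
  recurse(integer(), 0L)
  out
}

best_modularity <- function(g) {
  parts <- all_partitions(igraph::gorder(g))
  max(vapply(parts, function(m) igraph::modularity(g, m), 0))
}

# Closed-form natural connectivity of the complete graph K_n:
# eigenvalues are (n-1) once and -1 with multiplicity (n-1).
nc_complete <- function(n) {
  log((exp(n - 1) + (n - 1) * exp(-1)) / n)
}

# Small multi-kingdom dataset for pipeline-level tests.
tiny_dataset <- function(seed = 3, n_samples = 40) {
  make_synthetic_dataset(
    precision_spec(c(fungi = 8, bacteria = 8), topology = "band",
                   cross_kingdom_density = 0.05, seed = seed),
    n_samples = n_samples, mean_depth = 800, n_plant_species = 6,
    n_env_vars = 4, seed = seed)
}
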