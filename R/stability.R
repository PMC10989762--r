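#' Natural connectivity
#'
#' The natural connectivity of a graph is
#' `ln( (1/N) * sum_i exp(lambda_i) )` over the eigenvalues of the unsigned,
#' unweighted adjacency matrix - the log of the average weighted count of
#' closed walks, a spectral measure of routing redundancy. Computed with an
#' overflow-safe log-sum-exp, so dense graphs with large leading eigenvalues
#' are handled exactly. An edgeless graph has value 0.
#'
#' @param net A `signed_network`, igraph graph, or adjacency matrix.
#' @return A single number.
#' @examples
#' natural_connectivity(igraph::make_full_graph(4))  # ln((e^3 + 3/e)/4)
#' @export
natural_connectivity <- function(net) {
  a <- if (is.matrix(net)) {
    (unname(net) != 0) * 1
  } else {
    g <- as_sn_graph(net)
    igraph::as_adjacency_matrix(unsigned_graph(g), sparse = FALSE)
  }
  n <- nrow(a)
  if (n < 1) stop2("network must have at least one node")
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  logsumexp(ev) - log(n)
}

#' Natural-connectivity decay under random node removal
#'
#' Per replicate, removes uniformly random nodes one at a time until
#' `max_fraction` of nodes is gone, recording the natural connectivity of
#' the remaining graph after each removal. The replicate-averaged curve is
#' fit by ordinary least squares against the fraction removed; the smaller
#' the absolute slope, the more stable the network.
#'
#' Raw natural connectivity grows with network size and density, so raw
#' slopes are only comparable between graphs on the same scale. For
#' comparisons across differently sized networks (the kingdom
#' addition/removal experiments) set `normalize = TRUE`, which rescales the
#' curve by its unperturbed value so the slope measures proportional decay.
#'
#' @param net A `signed_network` or igraph graph with >= 4 nodes.
#' @param max_fraction Fraction of nodes to remove (default 0.5).
#' @param n_replicates Number of random removal orders (default 100).
#' @param seed Integer seed.
#' @param normalize Divide the curve by its value at fraction 0.
#' @return Object of class `stability_curve`: a data frame
#'   (`fraction_removed`, `mean_nc`, `sd_nc`) with attributes `slope`,
#'   `r_squared`, `n_replicates`, `seed`, `normalized`.
#' @export
robustness_curve <- function(net, max_fraction = 0.5, n_replicates = 100L,
                             seed = 1L, normalize = FALSE) {
  g <- unsigned_graph(as_sn_graph(net))
  n <- igraph::gorder(g)
  if (n < 4) stop2("need at least 4 nodes")
  if (!is.numeric(max_fraction) || max_fraction <= 0 || max_fraction > 0.5)
    stop2("max_fraction must lie in (0, 0.5]")
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- (unname(a) != 0) * 1
  n_remove <- floor(max_fraction * n)
  frac <- c(0, seq_len(n_remove) / n)
  nc0 <- natural_connectivity(a)
  curves <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      order_removed <- sample.int(n, n_remove)
      vapply(seq_len(n_remove), function(i) {
        keep <- setdiff(seq_len(n), order_removed[seq_len(i)])
        natural_connectivity(a[keep, keep, drop = FALSE])
      }, 0)
    }, numeric(n_remove))
  })
  curves <- rbind(rep(nc0, n_replicates),
                  matrix(curves, nrow = n_remove))
  mean_nc <- rowMeans(curves)
  sd_nc <- apply(curves, 1, stats::sd)
  if (normalize && nc0 > 0) {
    mean_nc <- mean_nc / nc0
    sd_nc <- sd_nc / nc0
  }
  if (stats::var(mean_nc) == 0) {
    slope <- 0; r2 <- NA_real_  # flat curve (e.g. edgeless graph)
  } else {
    fit <- stats::lm(mean_nc ~ frac)
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  out <- data.frame(fraction_removed = frac, mean_nc = mean_nc,
                    sd_nc = sd_nc)
  structure(out,
            slope = slope,
            r_squared = r2,
            normalized = normalize,
            n_replicates = n_replicates, seed = seed,
            class = c("stability_curve", "data.frame"))
}

#' Remove one kingdom from a multi-kingdom network
#'
#' Deletes the kingdom's nodes and all incident edges. The edge conservation
#' identity `E(multi) = E(result) + E(incident to removed nodes)` holds
#' exactly.
#'
#' @param net A `signed_network` with kingdom vertex labels.
#' @param kingdom Kingdom name to remove.
#' @return A `signed_network` without that kingdom.
#' @export
remove_kingdom <- function(net, kingdom) {
  g <- as_sn_graph(net)
  kl <- igraph::vertex_attr(g, "kingdom")
  if (is.null(kl)) stop2("network has no kingdom labels")
  drop <- which(kl == kingdom)
  if (length(drop) == igraph::gorder(g))
    stop2("removing '", kingdom, "' would remove every node")
  g2 <- igraph::delete_vertices(g, drop)
  signed_network(g2,
                 penalty = if (inherits(net, "signed_network"))
                   net$penalty else NA_real_,
                 seed = if (inherits(net, "signed_network"))
                   net$seed else NA_integer_)
}

#' Kingdom addition experiment
#'
#' Quantifies how adding one kingdom's taxa changes a network's topology and
#' stability (the "+F"-style experiments). Two modes:
#' * `"reinfer"` (default): the full inference pipeline is rerun on the
#'   concatenation of the base tables and the added kingdom's table - the
#'   faithful but slower route.
#' * `"induce"`: the subgraph of an existing multi-kingdom network induced
#'   on the union of the base and added kingdoms - fast, but reuses the
#'   penalty selected for the full network.
#'
#' @param base A [count_table] or list of them (the base kingdoms).
#' @param added A [count_table] for the kingdom being added.
#' @param mode `"reinfer"` or `"induce"`.
#' @param multi_net For `mode = "induce"`: the existing multi-kingdom
#'   `signed_network`.
#' @param stability Compute robustness curves for the base and augmented
#'   networks (default TRUE).
#' @param n_replicates,max_fraction Passed to [robustness_curve()].
#' @param seed Seed for inference and stability replicates.
#' @param ... Passed to [infer_network()] in reinfer mode.
#' @return List of class `composition_experiment`: `mode`, `net` (augmented),
#'   `base_net`, `topology`, `base_topology`, and (if requested) `curve`,
#'   `base_curve`.
#' @export
add_kingdom <- function(base, added, mode = c("reinfer", "induce"),
                        multi_net = NULL, stability = TRUE,
                        n_replicates = 100L, max_fraction = 0.5,
                        seed = 1L, ...) {
  mode <- match.arg(mode)
  if (mode == "reinfer") {
    if (inherits(base, "count_table")) base <- list(base)
    stopifnot(inherits(added, "count_table"))
    base_net <- infer_network(merge_kingdoms(base), seed = seed, ...)
    net <- infer_network(merge_kingdoms(c(base, list(added))),
                         seed = seed, ...)
  } else {
    if (is.null(multi_net)) stop2("induce mode needs multi_net")
    g <- as_sn_graph(multi_net)
    kl <- igraph::vertex_attr(g, "kingdom")
    base_kingdoms <- if (is.character(base)) base else
      unique(unlist(lapply(if (inherits(base, "count_table")) list(base)
                           else base,
                           function(t) unique(t$labels$kingdom))))
    added_kingdom <- if (is.character(added)) added else
      unique(added$labels$kingdom)
    unknown <- setdiff(c(base_kingdoms, added_kingdom), unique(kl))
    if (length(unknown) > 0)
      stop2("unknown kingdom(s): ", paste(unknown, collapse = ", "))
    base_net <- signed_network(
      igraph::induced_subgraph(g, which(kl %in% base_kingdoms)))
    net <- signed_network(
      igraph::induced_subgraph(g, which(kl %in% c(base_kingdoms,
                                                  added_kingdom))))
  }
  out <- list(mode = mode, net = net, base_net = base_net,
              topology = topology_summary(net, seed = seed),
              base_topology = topology_summary(base_net, seed = seed))
  if (stability) {
    # normalized curves: slopes comparable across the two network sizes
    out$curve <- robustness_curve(net, max_fraction, n_replicates,
                                  seed = seed, normalize = TRUE)
    out$base_curve <- robustness_curve(base_net, max_fraction, n_replicates,
                                       seed = seed, normalize = TRUE)
  }
  structure(out, class = "composition_experiment")
}

#' @export
print.composition_experiment <- function(x, ...) {
  cat(sprintf("<composition_experiment> mode=%s\n", x$mode))
  cat(sprintf("  base:      N=%d E=%d\n", x$base_topology$node_count,
              x$base_topology$edge_count))
  cat(sprintf("  augmented: N=%d E=%d\n", x$topology$node_count,
              x$topology$edge_count))
  if (!is.null(x$curve))
    cat(sprintf("  |slope| base=%.4f augmented=%.4f\n",
                abs(attr(x$base_curve, "slope")),
                abs(attr(x$curve, "slope"))))
  invisible(x)
}
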