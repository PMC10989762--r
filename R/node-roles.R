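#' Detect modules with seeded Louvain
#'
#' Module (community) detection on the unsigned, unweighted graph, used both
#' for the modularity summary and for node-role classification so that the
#' two agree on the same partition.
#'
#' @param net A `signed_network` or igraph graph.
#' @param seed Integer seed (Louvain uses the R RNG).
#' @return Named integer vector mapping node name to module id, of class
#'   `module_partition`, with attributes `method` and `seed`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- unsigned_graph(as_sn_graph(net))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  out <- as.integer(memb)
  names(out) <- igraph::V(g)$name %||% as.character(seq_along(out))
  structure(out, method = "louvain", seed = seed, class = "module_partition")
}

# Matrix of per-node link counts into each module: nodes x modules.
module_link_counts <- function(g, partition) {
  n <- igraph::gorder(g)
  memb <- as.integer(partition)
  if (length(memb) != n) stop2("partition must cover all nodes")
  mods <- sort(unique(memb))
  el <- igraph::as_edgelist(g, names = FALSE)
  ends <- c(el[, 1], el[, 2])                 # each edge seen from both ends
  other_mod <- memb[c(el[, 2], el[, 1])]      # module of the opposite end
  tab <- table(factor(ends, levels = seq_len(n)),
               factor(other_mod, levels = mods))
  k <- matrix(as.integer(tab), n, length(mods),
              dimnames = list(igraph::V(g)$name %||% as.character(seq_len(n)),
                              mods))
  list(k = k, memb = memb, mods = mods)
}

#' Within-module degree z-score
#'
#' For node i in module s, `z_i = (k_is - mean_s) / sd_s`, where `k_is` is
#' the number of links from i into its own module and mean/sd are taken over
#' the members of s (sd with the n-1 denominator; a module with zero
#' variance, or a single member, yields z = 0 for its nodes).
#'
#' @param net A `signed_network` or igraph graph.
#' @param partition A [detect_modules()] partition (or any integer vector).
#' @return Named numeric vector of z-scores.
#' @export
within_module_z <- function(net, partition) {
  g <- as_sn_graph(net)
  mlc <- module_link_counts(g, partition)
  k_own <- mlc$k[cbind(seq_len(nrow(mlc$k)), match(mlc$memb, mlc$mods))]
  z <- numeric(length(k_own))
  for (s in mlc$mods) {
    in_s <- mlc$memb == s
    mu <- mean(k_own[in_s])
    sdv <- stats::sd(k_own[in_s])
    z[in_s] <- if (is.na(sdv) || sdv == 0) 0 else (k_own[in_s] - mu) / sdv
  }
  names(z) <- rownames(mlc$k)
  z
}

#' Participation coefficient
#'
#' `c_i = 1 - sum_s (k_is / k_i)^2` over modules s; 0 when all of a node's
#' links stay within one module, approaching `1 - 1/M` when links are spread
#' evenly over M modules. Degree-0 nodes get c = 0.
#'
#' @inheritParams within_module_z
#' @return Named numeric vector of participation coefficients in [0, 1].
#' @export
participation_coefficient <- function(net, partition) {
  g <- as_sn_graph(net)
  mlc <- module_link_counts(g, partition)
  deg <- rowSums(mlc$k)
  frac2 <- (mlc$k / pmax(deg, 1))^2
  cc <- 1 - rowSums(frac2)
  cc[deg == 0] <- 0
  names(cc) <- rownames(mlc$k)
  cc
}

#' Classify nodes into topological roles from the z-c plane
#'
#' Uses the classical thresholds from pollination-network analysis:
#' peripheral (z < z_threshold, c <= c_threshold), connector
#' (z < z_threshold, c > c_threshold), module hub (z >= z_threshold,
#' c <= c_threshold), network hub (z >= z_threshold, c > c_threshold).
#' Boundary convention: z exactly at the threshold counts as hub, c exactly
#' at the threshold counts as non-connector.
#'
#' @param z,c Numeric vectors from [within_module_z()] and
#'   [participation_coefficient()] (matched by name when named).
#' @param z_threshold,c_threshold Role thresholds (defaults 2.5 and 0.62).
#' @param kingdom Optional kingdom label per node for the connector tally.
#' @return Data frame of class `node_roles` (`node`, `kingdom`, `z`, `c`,
#'   `role`) with attribute `connector_counts` (named integer vector per
#'   kingdom) when kingdoms are supplied.
#' @examples
#' classify_roles(z = c(3, 0), c = c(0.7, 0))$role
#' @export
classify_roles <- function(z, c, z_threshold = 2.5, c_threshold = 0.62,
                           kingdom = NULL) {
  if (length(z) != length(c)) stop2("z and c must have equal length")
  if (!is.null(names(z)) && !is.null(names(c))) c <- c[names(z)]
  hub <- z >= z_threshold
  conn <- c > c_threshold
  role <- ifelse(hub & conn, "network hub",
          ifelse(hub, "module hub",
          ifelse(conn, "connector", "peripheral")))
  # note: the argument `c` shadows base::c inside this function
  role <- factor(role, levels = base::c("peripheral", "connector",
                                        "module hub", "network hub"))
  out <- data.frame(node = names(z) %||% as.character(seq_along(z)),
                    kingdom = if (is.null(kingdom)) NA_character_ else
                      as.character(kingdom),
                    z = as.numeric(z), c = as.numeric(c), role = role,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("node_roles", "data.frame")
  if (!is.null(kingdom)) {
    tab <- table(kingdom = out$kingdom[out$role == "connector"])
    counts <- stats::setNames(as.integer(tab), names(tab))
    attr(out, "connector_counts") <- counts
  }
  out
}

#' Full node-role analysis of a network
#'
#' Convenience wrapper: detects modules, computes z and c, classifies roles,
#' and attaches kingdoms from the network's vertex attributes.
#'
#' @param net A `signed_network` or igraph graph.
#' @param seed Seed for module detection.
#' @param ... Passed to [classify_roles()].
#' @return A `node_roles` data frame (see [classify_roles()]) with the
#'   partition in attribute `partition`.
#' @export
node_roles <- function(net, seed = 1L, ...) {
  g <- as_sn_graph(net)
  part <- detect_modules(g, seed = seed)
  z <- within_module_z(g, part)
  cc <- participation_coefficient(g, part)
  out <- classify_roles(z, cc,
                        kingdom = igraph::vertex_attr(g, "kingdom"), ...)
  attr(out, "partition") <- part
  out
}
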