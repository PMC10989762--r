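#' Decompose a network's edges by kingdom pair
#'
#' Assigns every edge to exactly one unordered kingdom pair and counts
#' positive and negative edges per pair, plus within- versus cross-kingdom
#' totals.
#'
#' @param net A `signed_network` (or igraph graph) whose vertices all carry
#'   a `kingdom` attribute.
#' @return Data frame of class `link_decomposition` with columns
#'   `kingdom_a`, `kingdom_b`, `within`, `edges`, `positive`, `negative`,
#'   and attributes `within_total`, `cross_total`.
#' @export
decompose_links <- function(net) {
  g <- as_sn_graph(net)
  kl <- igraph::vertex_attr(g, "kingdom")
  if (is.null(kl) || anyNA(kl)) stop2("every node needs a kingdom label")
  el <- igraph::as_edgelist(g, names = FALSE)
  s <- igraph::edge_attr(g, "sign")
  ka <- kl[el[, 1]]; kb <- kl[el[, 2]]
  lo <- pmin(ka, kb); hi <- pmax(ka, kb)
  key <- paste(lo, hi, sep = "\r")
  agg <- function(x) tapply(x, key, sum)
  if (nrow(el) == 0) {
    out <- data.frame(kingdom_a = character(), kingdom_b = character(),
                      within = logical(), edges = integer(),
                      positive = integer(), negative = integer())
  } else {
    cnt <- table(key)
    pos <- agg(s > 0); neg <- agg(s < 0)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    out <- data.frame(
      kingdom_a = vapply(parts, `[`, "", 1),
      kingdom_b = vapply(parts, `[`, "", 2),
      edges = as.integer(cnt),
      positive = as.integer(pos[names(cnt)]),
      negative = as.integer(neg[names(cnt)]),
      stringsAsFactors = FALSE)
    out$within <- out$kingdom_a == out$kingdom_b
    out <- out[order(!out$within, out$kingdom_a, out$kingdom_b),
               c("kingdom_a", "kingdom_b", "within", "edges",
                 "positive", "negative")]
    rownames(out) <- NULL
  }
  structure(out,
            within_total = sum(out$edges[out$within]),
            cross_total = sum(out$edges[!out$within]),
            class = c("link_decomposition", "data.frame"))
}

#' Expected link proportions for a focal kingdom
#'
#' Under indiscriminate linking, the proportion of a focal kingdom's
#' cross-kingdom links expected to land in kingdom k is simply k's share of
#' the non-focal node pool: `p_k = n_k / sum_{j != focal} n_j`.
#'
#' @param node_counts Named integer vector of node counts per kingdom.
#' @param focal Name of the focal kingdom (present in `node_counts`).
#' @return Named numeric vector of proportions over the non-focal kingdoms,
#'   summing to 1.
#' @examples
#' expected_link_proportions(
#'   c(plants = 102, nematodes = 34, fungi = 178, bacteria = 1160,
#'     archaea = 76), focal = "fungi")
#' @export
expected_link_proportions <- function(node_counts, focal) {
  if (is.null(names(node_counts))) stop2("node_counts must be named")
  if (!focal %in% names(node_counts))
    stop2("focal kingdom '", focal, "' not in node_counts")
  others <- node_counts[setdiff(names(node_counts), focal)]
  if (length(others) == 0 || sum(others) == 0)
    stop2("no non-focal nodes")
  others / sum(others)
}

#' Link-preference deviates
#'
#' Difference between observed and expected link proportions per kingdom,
#' in the same units as the inputs (percentage points when given
#' percentages). The deviates sum to zero up to rounding.
#'
#' @param observed,expected Named numeric vectors over the same kingdoms.
#' @return Named numeric vector `observed - expected`.
#' @export
preference_deviates <- function(observed, expected) {
  if (is.null(names(observed)) || is.null(names(expected)))
    stop2("observed and expected must be named")
  if (!setequal(names(observed), names(expected)))
    stop2("mismatched kingdom keys: ",
          paste(union(setdiff(names(observed), names(expected)),
                      setdiff(names(expected), names(observed))),
                collapse = ", "))
  observed - expected[names(observed)]
}

#' Erdos-Renyi null ensemble for a negative-edge proportion
#'
#' Generates `n_random` G(n, m) random graphs with the same node set (labels
#' preserved) and exactly the observed edge count, reassigns the observed
#' multiset of edge signs randomly to the new edges (preserving the global
#' positive:negative ratio exactly), and recomputes the statistic: the
#' negative-edge proportion among edges joining `group_a` to `group_b`.
#' The Z-score is `(V_observed - mean_randomized) / sd_randomized`.
#'
#' @param net A `signed_network` (or igraph with `sign` edge attribute).
#' @param group_a,group_b Node predicates: logical vectors over vertices, or
#'   functions taking the vertex data frame (columns `name`, `kingdom`,
#'   `guild`) and returning a logical vector.
#' @param n_random Ensemble size (default 999).
#' @param seed Integer seed.
#' @return List of class `null_ensemble_result`: `observed`,
#'   `ensemble_mean`, `ensemble_sd`, `z`, `n_random`, `seed`,
#'   `degenerate` (TRUE when the ensemble sd is 0 and Z is undefined).
#' @export
er_null_negative_proportion <- function(net, group_a, group_b,
                                        n_random = 999L, seed = 1L) {
  g <- as_sn_graph(net)
  n <- igraph::gorder(g)
  m <- igraph::gsize(g)
  signs <- igraph::edge_attr(g, "sign")
  vdf <- data.frame(
    name = igraph::V(g)$name %||% as.character(seq_len(n)),
    kingdom = igraph::vertex_attr(g, "kingdom") %||% NA_character_,
    guild = igraph::vertex_attr(g, "guild") %||% NA_character_,
    stringsAsFactors = FALSE)
  resolve <- function(grp) {
    out <- if (is.function(grp)) grp(vdf) else grp
    if (!is.logical(out) || length(out) != n)
      stop2("group predicate must yield one logical per node")
    out
  }
  in_a <- resolve(group_a); in_b <- resolve(group_b)
  if (!any(in_a) || !any(in_b)) stop2("groups must be non-empty")
  if (!any(signs < 0)) stop2("network has no negative edges")

  stat <- function(el, s) {
    qual <- (in_a[el[, 1]] & in_b[el[, 2]]) | (in_b[el[, 1]] & in_a[el[, 2]])
    if (!any(qual)) return(NA_real_)
    mean(s[qual] < 0)
  }
  observed <- stat(igraph::as_edgelist(g, names = FALSE), signs)
  draws <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      gr <- igraph::sample_gnm(n, m)
      stat(igraph::as_edgelist(gr, names = FALSE), sample(signs))
    }, 0)
  })
  ensemble_mean <- mean(draws, na.rm = TRUE)
  ensemble_sd <- stats::sd(draws, na.rm = TRUE)
  z <- z_score(observed, ensemble_mean, ensemble_sd)
  structure(
    list(observed = observed, ensemble_mean = ensemble_mean,
         ensemble_sd = ensemble_sd, z = z, n_random = n_random,
         seed = seed, degenerate = is.na(z)),
    class = "null_ensemble_result")
}

#' @export
print.null_ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble_result> observed=%.4f null=%.4f +/- %.4f Z=%s (n=%d)\n",
    x$observed, x$ensemble_mean, x$ensemble_sd,
    if (x$degenerate) "undefined" else sprintf("%.3f", x$z), x$n_random))
  invisible(x)
}
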