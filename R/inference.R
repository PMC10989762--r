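#' Per-kingdom centred log-ratio transform
#'
#' Applies the CLR transform within each kingdom block separately and
#' concatenates the results: for each sample and block,
#' `log(x + pseudocount)` centred by the sample's within-block mean log.
#' Treating each kingdom as its own composition is what extends the sparse
#' inverse-covariance approach across sequencing domains with unrelated
#' library sizes; the binary plant block passes through the same transform
#' with 0/1 treated as counts.
#'
#' @param table A `multi_kingdom_table` from [merge_kingdoms()].
#' @param pseudocount Positive value added before taking logs (default 1).
#' @return Numeric samples x taxa matrix of class `latent_matrix` with
#'   attributes `blocks` (named list of column index vectors) and `labels`
#'   (taxon label data.frame). Each sample's values within a block sum to 0.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "multi_kingdom_table"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop2("pseudocount must be > 0")
  mats <- lapply(table$blocks, function(b) {
    if (n_taxa(b) == 0) stop2("empty kingdom block")
    lg <- log(t(b$counts) + pseudocount)   # samples x taxa
    lg - rowMeans(lg)
  })
  out <- do.call(cbind, unname(mats))
  sizes <- vapply(mats, ncol, 1L)
  ends <- cumsum(sizes)
  blocks <- Map(function(s, e) seq.int(s, e), ends - sizes + 1L, ends)
  names(blocks) <- names(table$blocks)
  structure(out, blocks = blocks, labels = mk_labels(table),
            class = c("latent_matrix", "matrix", "array"))
}

# Column-standardise, mapping zero-variance columns to all zeros.
standardize_columns <- function(x) {
  x <- scale(unclass(x), center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(x^2))
  x <- sweep(x, 2, ifelse(sds > 0, sds, 1), `/`)
  x
}

# Default penalty path: n_lambda log-spaced values from the maximum absolute
# off-diagonal empirical covariance of the standardised columns (i.e. the
# maximum absolute correlation) down to ratio * that maximum. The node-wise
# lasso runs on the same standardised scale, so the path's top end yields an
# empty graph.
lambda_path <- function(latent, n_lambda = 20L, ratio = 0.01) {
  x <- standardize_columns(latent)
  s <- crossprod(x) / nrow(x)
  diag(s) <- 0
  lmax <- max(abs(s))
  if (lmax <= 0) stop2("degenerate data: zero covariance")
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# Fit the Meinshausen-Buhlmann node-wise lasso over a penalty path.
# Returns, per penalty, the OR-symmetrised support with signed weights.
# latent: samples x taxa matrix (centred internally); penalties decreasing.
mb_fit_path <- function(latent, penalties) {
  x <- standardize_columns(latent)  # correlation scale, as in huge::huge.mb
  n <- nrow(x); p <- ncol(x)
  if (p < 3) stop2("need at least 3 taxa")
  if (any(penalties <= 0)) {
    if (p > n) stop2("penalty 0 with more taxa than samples is unidentifiable")
    stop2("penalties must be > 0")
  }
  if (is.unsorted(rev(penalties), strictly = TRUE))
    stop2("penalties must be strictly decreasing")
  nl <- length(penalties)
  # beta[j, k, l]: coefficient of predictor k in the regression of node j
  beta <- array(0, dim = c(p, p, nl))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(x[, -j, drop = FALSE], x[, j],
                          family = "gaussian", lambda = penalties,
                          standardize = FALSE, intercept = FALSE)
    b <- as.matrix(fit$beta)
    # glmnet may return fewer columns if it stops early; pad with last
    if (ncol(b) < nl)
      b <- cbind(b, b[, rep(ncol(b), nl - ncol(b)), drop = FALSE])
    beta[j, -j, ] <- b[, seq_len(nl)]
  }
  lapply(seq_len(nl), function(l) {
    bl <- beta[, , l]
    support <- (bl != 0) | (t(bl) != 0)    # OR rule
    diag(support) <- FALSE
    # sign from the larger-magnitude directed coefficient; weight = mean |.|
    use_t <- abs(t(bl)) > abs(bl)
    signs <- sign(ifelse(use_t, t(bl), bl))
    weights <- (abs(bl) + abs(t(bl))) / 2
    signs[!support] <- 0
    weights[!support] <- 0
    dimnames(support) <- dimnames(signs) <- dimnames(weights) <-
      list(colnames(latent), colnames(latent))
    list(support = support, sign = signs, weight = weights,
         penalty = penalties[l])
  })
}

#' Sparse neighbourhood selection at a single penalty
#'
#' One L1-penalised linear regression per taxon on all other (CLR) columns;
#' the edge support is symmetrised by the OR rule, the edge sign is the sign
#' of the directed coefficient with the larger absolute magnitude, and the
#' weight is the mean of the two coefficient magnitudes.
#'
#' @param latent A `latent_matrix` from [clr_transform()] (any numeric
#'   samples x taxa matrix is accepted).
#' @param penalty Positive lasso penalty on the `glmnet` scale
#'   (`(1/2n)RSS + penalty * ||beta||_1`).
#' @return List with symmetric logical `support`, numeric `sign` and
#'   `weight` matrices (zero diagonal), and the `penalty` used.
#' @export
mb_neighborhood_selection <- function(latent, penalty) {
  stopifnot(length(penalty) == 1L)
  mb_fit_path(latent, penalty)[[1]]
}

#' StARS penalty selection by subsampling
#'
#' For each penalty on a decreasing path, the node-wise lasso is refit on
#' `n_subsamples` random subsamples (fraction `subsample_fraction`, without
#' replacement); the edge-selection frequencies f give a mean edge
#' instability `2 f (1 - f)` averaged over all taxon pairs. The selected
#' penalty is the smallest (densest) one whose running-supremum instability,
#' accumulated from the sparse end of the path, stays at or below `beta`.
#'
#' @param latent A `latent_matrix` (samples x taxa).
#' @param penalties Decreasing penalty path; defaults to 20 log-spaced
#'   values from the maximum absolute empirical covariance down to 1/100 of
#'   it.
#' @param n_subsamples Number of subsamples (default 50).
#' @param subsample_fraction Fraction of samples per subsample (default 0.8).
#' @param beta Instability threshold (default 0.05).
#' @param seed Integer seed for the subsampling.
#' @return List of class `stars_path`: `penalty` (selected), `index`,
#'   `penalties`, `instability`, `monotone_instability`, `edge_frequency`
#'   (list of symmetric frequency matrices), and the StARS parameters.
#' @export
stars_select <- function(latent, penalties = NULL, n_subsamples = 50L,
                         subsample_fraction = 0.8, beta = 0.05, seed = 1L) {
  if (is.null(penalties)) penalties <- lambda_path(latent)
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction >= 1)
    stop2("subsample_fraction must lie in (0, 1)")
  n <- nrow(latent); p <- ncol(latent)
  b <- max(4L, floor(subsample_fraction * n))
  nl <- length(penalties)
  up <- upper.tri(matrix(0, p, p))
  freq <- matrix(0, sum(up), nl)
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      rows <- sample.int(n, b)
      fits <- mb_fit_path(unclass(latent)[rows, , drop = FALSE], penalties)
      for (l in seq_len(nl))
        freq[, l] <- freq[, l] + fits[[l]]$support[up]
    }
  })
  f <- freq / n_subsamples
  instability <- colMeans(2 * f * (1 - f))
  mono <- cummax(instability)  # running supremum from sparse to dense
  ok <- which(mono <= beta)
  if (length(ok) == 0) {
    warn2("no penalty meets the instability threshold; returning the ",
          "sparsest penalty")
    index <- 1L
  } else {
    index <- max(ok)
  }
  fm <- lapply(seq_len(nl), function(l) {
    m <- matrix(0, p, p, dimnames = list(colnames(latent), colnames(latent)))
    m[up] <- f[, l]
    m + t(m)
  })
  structure(
    list(penalty = penalties[index], index = index, penalties = penalties,
         instability = instability, monotone_instability = mono,
         edge_frequency = fm, n_subsamples = n_subsamples,
         subsample_fraction = subsample_fraction, beta = beta, seed = seed),
    class = "stars_path")
}

#' @export
print.stars_path <- function(x, ...) {
  cat(sprintf(
    "<stars_path> %d penalties, selected %.4g (index %d), instability %.4f\n",
    length(x$penalties), x$penalty, x$index, x$instability[x$index]))
  invisible(x)
}

#' Assemble a signed network from a neighbourhood-selection fit
#'
#' @param fit A fit from [mb_neighborhood_selection()] (list with `support`,
#'   `sign`, `weight`).
#' @param labels Data frame with columns `taxon_id`, `kingdom` and
#'   optionally `guild`, covering every taxon in the fit.
#' @param penalty,seed Provenance recorded on the network.
#' @return An object of class `signed_network` wrapping an undirected
#'   igraph graph whose vertices carry `kingdom`/`guild` attributes and
#'   whose edges carry `sign` (+1/-1) and `weight` attributes.
#' @export
build_network <- function(fit, labels, penalty = fit$penalty %||% NA_real_,
                          seed = NA_integer_) {
  taxa <- colnames(fit$support)
  if (is.null(taxa)) taxa <- sprintf("taxon_%d", seq_len(ncol(fit$support)))
  missing <- setdiff(taxa, labels$taxon_id)
  if (length(missing) > 0)
    stop2("unlabeled taxa: ", paste(utils::head(missing, 5), collapse = ", "))
  labels <- labels[match(taxa, labels$taxon_id), , drop = FALSE]
  idx <- which(fit$support & upper.tri(fit$support), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  g <- igraph::set_vertex_attr(g, "kingdom", value = labels$kingdom)
  g <- igraph::set_vertex_attr(g, "guild",
                               value = as.character(labels$guild %||%
                                                      NA_character_))
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "sign", value = fit$sign[idx])
    g <- igraph::set_edge_attr(g, "weight", value = fit$weight[idx])
  }
  signed_network(g, penalty = penalty, seed = seed)
}

#' Signed network container
#'
#' Wraps an undirected igraph graph with vertex attributes `kingdom` and
#' `guild` and edge attributes `sign` and `weight`, plus inference
#' provenance. Most analysis functions in the package accept either a
#' `signed_network` or a bare igraph graph (missing signs default to +1).
#'
#' @param graph An undirected igraph graph.
#' @param penalty,seed Provenance.
#' @return An object of class `signed_network`.
#' @export
signed_network <- function(graph, penalty = NA_real_, seed = NA_integer_) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  if (any(igraph::which_loop(graph))) stop2("self-loops are not allowed")
  if (any(igraph::which_multiple(graph)))
    stop2("multiple edges between a pair are not allowed")
  if (is.null(igraph::edge_attr(graph, "sign")))
    graph <- igraph::set_edge_attr(graph, "sign",
                                   value = rep(1, igraph::gsize(graph)))
  structure(list(graph = graph, penalty = penalty, seed = seed),
            class = "signed_network")
}

# Coerce signed_network / igraph to igraph with a sign edge attribute.
as_sn_graph <- function(net) {
  g <- if (inherits(net, "signed_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::edge_attr(g, "sign")))
    g <- igraph::set_edge_attr(g, "sign", value = rep(1, igraph::gsize(g)))
  g
}

#' @export
print.signed_network <- function(x, ...) {
  g <- x$graph
  s <- igraph::edge_attr(g, "sign")
  cat(sprintf("<signed_network> %d nodes, %d edges (%d +, %d -)\n",
              igraph::gorder(g), igraph::gsize(g),
              sum(s > 0), sum(s < 0)))
  if (!is.na(x$penalty))
    cat(sprintf("  penalty %.4g, seed %s\n", x$penalty, x$seed))
  invisible(x)
}

#' Infer a signed multi-kingdom network end to end
#'
#' Convenience wrapper: CLR transform per kingdom block, StARS penalty
#' selection, refit of the node-wise lasso at the selected penalty on the
#' full data, and assembly of the labelled signed network.
#'
#' @inheritParams clr_transform
#' @inheritParams stars_select
#' @param ... Passed to [stars_select()].
#' @return A `signed_network` with attribute `stars` (the `stars_path`).
#' @export
infer_network <- function(table, pseudocount = 1, penalties = NULL,
                          seed = 1L, ...) {
  latent <- clr_transform(table, pseudocount)
  sel <- stars_select(latent, penalties = penalties, seed = seed, ...)
  fit <- mb_neighborhood_selection(latent, sel$penalty)
  net <- build_network(fit, attr(latent, "labels"),
                       penalty = sel$penalty, seed = seed)
  attr(net, "stars") <- sel
  net
}
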