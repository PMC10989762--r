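#' Specification of a ground-truth sparse precision matrix
#'
#' Describes the block-structured conditional-dependence graph from which
#' synthetic multi-kingdom counts are drawn. Taxa are partitioned into
#' kingdom blocks; within-kingdom edges follow the chosen topology, while
#' cross-kingdom edges are placed uniformly at random between blocks.
#'
#' The nonzero off-diagonal entries of the precision matrix have fixed
#' magnitude `strength`; a fraction `negative_fraction` of the ground-truth
#' associations is negative. Because the sign of an association (partial
#' correlation) is the opposite of the precision-matrix entry's sign, the
#' recorded truth carries association signs, which is what network inference
#' is expected to recover.
#'
#' @param n_taxa_per_kingdom Named integer vector, taxa per kingdom
#'   (>= 2 kingdoms, >= 2 taxa each).
#' @param topology Within-kingdom edge structure: `"band"` (pairs within
#'   `bandwidth` of each other along the block ordering), `"cluster"` (two
#'   dense groups per block) or `"random"` (uniform pairs).
#' @param within_kingdom_density Fraction of the topology's candidate
#'   within-kingdom pairs that receive an edge.
#' @param cross_kingdom_density Fraction of all cross-kingdom pairs that
#'   receive an edge.
#' @param negative_fraction Fraction of ground-truth associations that are
#'   negative.
#' @param condition_cap Upper bound on the condition number of the returned
#'   precision matrix; the diagonal is boosted until
#'   `max(eigen)/min(eigen) <= condition_cap`.
#' @param bandwidth Band half-width for `topology = "band"`.
#' @param strength Magnitude of nonzero off-diagonal precision entries.
#' @param seed Integer seed controlling edge placement and sign assignment.
#' @return An object of class `precision_spec`.
#' @seealso [make_precision_matrix()]
#' @export
precision_spec <- function(n_taxa_per_kingdom,
                           topology = c("band", "cluster", "random"),
                           within_kingdom_density = 1,
                           cross_kingdom_density = 0.02,
                           negative_fraction = 0.35,
                           condition_cap = 100,
                           bandwidth = 1L,
                           strength = 0.3,
                           seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(names(n_taxa_per_kingdom)))
    names(n_taxa_per_kingdom) <- sprintf("K%d", seq_along(n_taxa_per_kingdom))
  if (length(n_taxa_per_kingdom) < 2L)
    stop2("need at least 2 kingdoms")
  if (any(n_taxa_per_kingdom < 2L))
    stop2("need at least 2 taxa per kingdom")
  if (!is_fraction(within_kingdom_density) ||
      !is_fraction(cross_kingdom_density) ||
      !is_fraction(negative_fraction))
    stop2("densities and negative_fraction must lie in [0, 1]")
  if (!is.numeric(condition_cap) || condition_cap <= 1)
    stop2("condition_cap must exceed 1")
  if (!is_count(bandwidth) || bandwidth < 1) stop2("bandwidth must be >= 1")
  if (!is.numeric(strength) || strength <= 0) stop2("strength must be > 0")
  structure(
    list(n_taxa_per_kingdom = as.integer(n_taxa_per_kingdom) |>
           stats::setNames(names(n_taxa_per_kingdom)),
         topology = topology,
         within_kingdom_density = within_kingdom_density,
         cross_kingdom_density = cross_kingdom_density,
         negative_fraction = negative_fraction,
         condition_cap = condition_cap,
         bandwidth = as.integer(bandwidth),
         strength = strength,
         seed = as.integer(seed)),
    class = "precision_spec")
}

# Candidate within-block pairs (global indices) for one block.
block_candidate_pairs <- function(offset, nt, topology, bandwidth) {
  idx <- offset + seq_len(nt)
  if (topology == "band") {
    pairs <- do.call(rbind, lapply(seq_len(bandwidth), function(d) {
      if (nt <= d) return(NULL)
      cbind(idx[seq_len(nt - d)], idx[seq_len(nt - d) + d])
    }))
    if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
    return(pairs)
  }
  if (topology == "cluster") {
    half <- split(idx, rep(1:2, length.out = nt))
    pairs <- do.call(rbind, lapply(half, function(g) {
      if (length(g) < 2) return(NULL)
      t(utils::combn(g, 2))
    }))
    if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
    return(pairs)
  }
  t(utils::combn(idx, 2))  # random: all within pairs are candidates
}

#' Build a ground-truth precision matrix and signed edge set
#'
#' Constructs a symmetric positive-definite precision matrix whose support is
#' exactly the ground-truth edge set implied by `spec`. Positive
#' definiteness is enforced by boosting the diagonal until the spectrum's
#' condition number is at most `spec$condition_cap` (a deterministic repair,
#' no rejection sampling).
#'
#' @param spec A [precision_spec()].
#' @return A list of class `precision_model` with elements
#'   `omega` (the precision matrix, taxa named `<kingdom>_<i>`),
#'   `truth` (data.frame `taxon_a`, `taxon_b`, `sign` with association signs
#'   in \{-1, +1\}), and `labels` (taxon_id/kingdom data.frame).
#' @examples
#' pm <- make_precision_matrix(precision_spec(c(fungi = 5, bacteria = 5)))
#' nrow(pm$truth)
#' min(eigen(pm$omega, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
make_precision_matrix <- function(spec) {
  stopifnot(inherits(spec, "precision_spec"))
  nt <- spec$n_taxa_per_kingdom
  p <- sum(nt)
  kingdom <- rep(names(nt), nt)
  taxon_id <- unlist(lapply(names(nt), function(k)
    sprintf("%s_%d", k, seq_len(nt[[k]]))), use.names = FALSE)
  offsets <- c(0L, cumsum(nt))[seq_along(nt)]

  with_seed(spec$seed, {
    within <- do.call(rbind, lapply(seq_along(nt), function(i)
      block_candidate_pairs(offsets[i], nt[[i]], spec$topology,
                            spec$bandwidth)))
    n_within <- round(spec$within_kingdom_density * nrow(within))
    if (n_within > nrow(within))
      stop2("infeasible within-kingdom density: ", n_within, " edges ",
            "requested but only ", nrow(within), " candidate pairs exist")
    within <- within[sample.int(nrow(within), n_within), , drop = FALSE]

    cross <- which(outer(kingdom, kingdom, `!=`) & upper.tri(diag(p)),
                   arr.ind = TRUE)
    n_cross <- round(spec$cross_kingdom_density * nrow(cross))
    if (n_cross > nrow(cross))
      stop2("infeasible cross-kingdom density")
    cross <- cross[sample.int(nrow(cross), n_cross), , drop = FALSE]

    edges <- rbind(within, unname(cross))
    m <- nrow(edges)
    sgn <- rep(1L, m)
    if (m > 0) {
      n_neg <- round(spec$negative_fraction * m)
      sgn[sample.int(m, n_neg)] <- -1L
    }

    omega <- diag(p)
    if (m > 0) {
      # association sign = -sign(precision off-diagonal)
      omega[edges] <- -sgn * spec$strength
      omega[edges[, 2:1, drop = FALSE]] <- -sgn * spec$strength
    }
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    lam_max <- max(ev); lam_min <- min(ev)
    delta <- max(0, (lam_max - spec$condition_cap * lam_min) /
                   (spec$condition_cap - 1))
    if (lam_min + delta <= 0) delta <- delta + 1e-8 - (lam_min + delta)
    omega <- omega + delta * diag(p)
    dimnames(omega) <- list(taxon_id, taxon_id)

    truth <- data.frame(
      taxon_a = taxon_id[edges[, 1]],
      taxon_b = taxon_id[edges[, 2]],
      sign = sgn,
      stringsAsFactors = FALSE)

    structure(
      list(omega = omega,
           truth = truth,
           labels = data.frame(taxon_id = taxon_id, kingdom = kingdom,
                               guild = NA_character_,
                               stringsAsFactors = FALSE)),
      class = "precision_model")
  })
}

#' Draw multi-kingdom counts from a logistic-normal multinomial model
#'
#' Latent per-sample abundances are drawn from the zero-mean Gaussian with
#' the given precision matrix, mapped to compositions by softmax, and counts
#' are drawn multinomially at the requested sequencing depths. This is the
#' standard generative model for benchmarking compositional network
#' inference: the counts carry the compositional closure that the centred
#' log-ratio transform is meant to undo.
#'
#' @param precision Symmetric positive-definite precision matrix
#'   (taxa x taxa, dimnames used as taxon ids).
#' @param n_samples Number of samples to draw.
#' @param depths Per-sample sequencing depths (positive integers, recycled).
#' @param seed Integer seed.
#' @return Integer matrix taxa x samples with attribute `latent`
#'   (samples x taxa Gaussian draws, useful for linking auxiliary tables).
#' @examples
#' pm <- make_precision_matrix(precision_spec(c(A = 3, B = 3)))
#' x <- sample_counts(pm$omega, n_samples = 4, depths = 1000, seed = 1)
#' colSums(x)  # all equal 1000
#' @export
sample_counts <- function(precision, n_samples, depths = 5000L, seed = 1L) {
  precision <- as.matrix(precision)
  p <- nrow(precision)
  if (!isSymmetric(unname(precision), tol = 1e-8))
    stop2("precision must be symmetric")
  ch <- tryCatch(chol(precision),
                 error = function(e) stop2("precision must be positive definite"))
  if (!is_count(n_samples) || n_samples < 1) stop2("n_samples must be >= 1")
  depths <- rep_len(as.integer(depths), n_samples)
  if (any(depths < 1)) stop2("depths must all be >= 1")

  # Sigma = Omega^{-1}; X = Z * chol(Sigma) gives rows ~ N(0, Sigma)
  sigma <- chol2inv(ch)
  cs <- chol(sigma)
  taxa <- rownames(precision) %||% sprintf("taxon_%d", seq_len(p))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    latent <- z %*% cs
    counts <- vapply(seq_len(n_samples), function(i) {
      w <- exp(latent[i, ] - max(latent[i, ]))
      as.integer(stats::rmultinom(1, depths[i], prob = w / sum(w)))
    }, integer(p))
    dimnames(counts) <- list(taxa, sprintf("sample_%d", seq_len(n_samples)))
    dimnames(latent) <- list(colnames(counts), taxa)
    attr(counts, "latent") <- latent
    counts
  })
}

#' Generate a binary plant species presence/absence table
#'
#' Emulates a vegetation survey recorded alongside soil samples. Optionally,
#' the first `ncol(latent)` species are linked to latent taxon abundances:
#' presence probability is a logistic function of the (standardised) latent
#' value, so the induced plant-taxon association is independent of
#' sequencing depth.
#'
#' @param n_species Number of plant species (rows).
#' @param n_samples Number of samples (columns).
#' @param latent Optional samples x k matrix of latent abundances to link
#'   the first k species to (e.g. the `latent` attribute of
#'   [sample_counts()]).
#' @param link_strength Logistic slope on the standardised latent value;
#'   0 makes all species independent of the counts.
#' @param base_prob Baseline presence probability per species, recycled.
#' @param seed Integer seed.
#' @return Binary integer matrix species x samples.
#' @export
sample_plant_table <- function(n_species, n_samples, latent = NULL,
                               link_strength = 2, base_prob = 0.3,
                               seed = 1L) {
  if (!is_count(n_species) || n_species < 1) stop2("n_species must be >= 1")
  if (!is_count(n_samples) || n_samples < 1) stop2("n_samples must be >= 1")
  k <- 0L
  if (!is.null(latent)) {
    latent <- as.matrix(latent)
    if (nrow(latent) != n_samples)
      stop2("latent must have one row per sample")
    k <- min(ncol(latent), n_species)
  }
  base_prob <- rep_len(base_prob, n_species)
  with_seed(seed, {
    eta <- matrix(stats::qlogis(base_prob), n_species, n_samples)
    if (k > 0) {
      zs <- scale(latent[, seq_len(k), drop = FALSE])
      eta[seq_len(k), ] <- eta[seq_len(k), ] + link_strength * t(zs)
    }
    tab <- matrix(stats::rbinom(n_species * n_samples, 1L,
                                stats::plogis(eta)),
                  n_species, n_samples)
    dimnames(tab) <- list(sprintf("plant_%d", seq_len(n_species)),
                          sprintf("sample_%d", seq_len(n_samples)))
    storage.mode(tab) <- "integer"
    tab
  })
}

#' Generate environmental metadata with a dominant gradient
#'
#' Produces a samples x variables matrix emulating soil/vegetation metadata:
#' the first variable tracks a latent elevation-like gradient (a stand-in
#' for soil pH, the dominant axis in mountain soils) with strength
#' `gradient_effect`; the remaining base variables are independent noise.
#' For each of `collinear_pairs`, a near-duplicate of an existing variable
#' (|Pearson r| > 0.7) is appended so the collinearity filter has real work
#' to do.
#'
#' @param n_samples Number of samples.
#' @param n_vars Number of base variables (>= 1).
#' @param gradient_effect Slope of variable 1 on the latent gradient;
#'   0 removes the gradient signal entirely.
#' @param collinear_pairs Number of near-duplicate variables to append.
#' @param seed Integer seed.
#' @return Numeric matrix samples x (n_vars + collinear_pairs) with
#'   attribute `gradient` (the latent gradient values).
#' @export
sample_environment <- function(n_samples, n_vars, gradient_effect = 1,
                               collinear_pairs = 0L, seed = 1L) {
  if (!is_count(n_vars) || n_vars < 1) stop2("n_vars must be >= 1")
  if (!is_count(collinear_pairs) || collinear_pairs < 0)
    stop2("collinear_pairs must be >= 0")
  with_seed(seed, {
    gradient <- sort(stats::rnorm(n_samples))
    env <- matrix(stats::rnorm(n_samples * n_vars), n_samples, n_vars)
    env[, 1] <- gradient_effect * gradient + stats::rnorm(n_samples, sd = 0.3)
    colnames(env) <- sprintf("var_%d", seq_len(n_vars))
    if (collinear_pairs > 0) {
      src <- rep_len(seq_len(n_vars), collinear_pairs)
      dup <- env[, src, drop = FALSE] +
        matrix(stats::rnorm(n_samples * collinear_pairs, sd = 0.25),
               n_samples, collinear_pairs)
      colnames(dup) <- sprintf("var_%d_dup", src)
      env <- cbind(env, dup)
    }
    rownames(env) <- sprintf("sample_%d", seq_len(n_samples))
    attr(env, "gradient") <- gradient
    env
  })
}

#' Generate a complete synthetic multi-kingdom dataset
#'
#' One call producing everything the pipeline consumes: per-kingdom count
#' tables drawn from a shared logistic-normal multinomial model with known
#' sparse precision structure, a correlated binary plant table, an
#' environmental matrix with a dominant gradient and planted collinear
#' pairs, and the ground-truth signed edge set.
#'
#' Defaults mirror the scale of a desk-size timberline soil survey:
#' 30 samples, log-normal sequencing depths around 5000 reads, three
#' microbial kingdoms, a 35% negative-association fraction.
#'
#' @param spec A [precision_spec()]; the default is a band graph over
#'   fungi (20), bacteria (20) and archaea (10).
#' @param n_samples Number of samples.
#' @param mean_depth,depth_sdlog Log-normal sequencing-depth parameters
#'   (median `mean_depth`, log-sd `depth_sdlog`).
#' @param n_plant_species Number of plant species in the binary table.
#' @param plant_link_taxa Number of leading taxa whose latent abundance
#'   drives linked plant presences.
#' @param plant_link_strength Logistic slope of those links.
#' @param n_env_vars,env_gradient_effect,env_collinear_pairs Passed to
#'   [sample_environment()].
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return An object of class `synthetic_dataset`: list with `counts`
#'   (named list of [count_table] per kingdom), `plant_table`, `environment`,
#'   `truth`, `latent` and `seed`.
#' @examples
#' ds <- make_synthetic_dataset(n_samples = 10, mean_depth = 500, seed = 42)
#' names(ds$counts)
#' @export
make_synthetic_dataset <- function(spec = precision_spec(
                                     c(fungi = 20, bacteria = 20, archaea = 10)),
                                   n_samples = 30L,
                                   mean_depth = 5000,
                                   depth_sdlog = 0.3,
                                   n_plant_species = 20L,
                                   plant_link_taxa = 3L,
                                   plant_link_strength = 2,
                                   n_env_vars = 10L,
                                   env_gradient_effect = 1,
                                   env_collinear_pairs = 2L,
                                   seed = 1L) {
  seed <- as.integer(seed)
  pm <- make_precision_matrix(spec)
  depths <- with_seed(seed, {
    pmax(50L, as.integer(round(stats::rlnorm(n_samples, log(mean_depth),
                                             depth_sdlog))))
  })
  counts_all <- sample_counts(pm$omega, n_samples, depths, seed = seed + 1L)
  latent <- attr(counts_all, "latent")
  kingdom <- pm$labels$kingdom
  counts <- lapply(split(seq_len(nrow(counts_all)), kingdom)[unique(kingdom)],
                   function(i) count_table(counts_all[i, , drop = FALSE],
                                           kingdom = kingdom[i]))
  plant_link_taxa <- min(plant_link_taxa, ncol(latent))
  plant <- sample_plant_table(
    n_plant_species, n_samples,
    latent = if (plant_link_taxa > 0)
      latent[, seq_len(plant_link_taxa), drop = FALSE] else NULL,
    link_strength = plant_link_strength, seed = seed + 2L)
  colnames(plant) <- colnames(counts_all)
  env <- sample_environment(n_samples, n_env_vars, env_gradient_effect,
                            env_collinear_pairs, seed = seed + 3L)
  rownames(env) <- colnames(counts_all)
  structure(
    list(counts = counts, plant_table = plant, environment = env,
         truth = pm$truth, labels = pm$labels, latent = latent, seed = seed),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d kingdoms, %d taxa, %d samples, %d truth edges\n",
    length(x$counts), sum(vapply(x$counts, n_taxa, 1L)),
    ncol(x$counts[[1]]$counts), nrow(x$truth)))
  invisible(x)
}
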