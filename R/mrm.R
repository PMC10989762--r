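# Distance matrices and multiple regression on distance matrices (MRM).

new_distance_matrix <- function(d, ids, metric) {
  dimnames(d) <- list(ids, ids)
  structure(d, metric = metric, class = c("distance_matrix", "matrix",
                                          "array"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa. A pair of
#' all-zero samples gets distance 0 with a warning.
#'
#' @param table A [count_table] or numeric matrix (taxa x samples).
#' @return Square symmetric matrix of class `distance_matrix`, zero
#'   diagonal, entries in [0, 1], attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (ncol(x) < 2) stop2("need at least 2 samples")
  ids <- colnames(x) %||% sprintf("sample_%d", seq_len(ncol(x)))
  num <- as.matrix(stats::dist(t(x), method = "manhattan"))
  tot <- outer(colSums(x), colSums(x), `+`)
  if (any(tot == 0 & upper.tri(tot)))
    warn2("all-zero sample pair; Bray-Curtis distance set to 0")
  d <- ifelse(tot == 0, 0, num / tot)
  diag(d) <- 0
  new_distance_matrix(d, ids, "bray_curtis")
}

#' Jaccard dissimilarity between samples on presence/absence
#'
#' `d = 1 - |intersection| / |union|` of the species presence sets of two
#' samples. An empty pair of samples gets distance 0 with a warning.
#'
#' @param table Binary matrix (species x samples); any nonzero entry counts
#'   as presence. A [count_table] is accepted.
#' @return Square symmetric `distance_matrix` with
#'   `metric = "jaccard"`.
#' @export
jaccard <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (ncol(x) < 2) stop2("need at least 2 samples")
  if (!all(x %in% c(0, 1))) stop2("jaccard expects a binary (0/1) table")
  ids <- colnames(x) %||% sprintf("sample_%d", seq_len(ncol(x)))
  inter <- crossprod(x)
  sizes <- colSums(x)
  uni <- outer(sizes, sizes, `+`) - inter
  if (any(uni == 0 & upper.tri(uni)))
    warn2("empty sample pair; Jaccard distance set to 0")
  d <- ifelse(uni == 0, 0, 1 - inter / uni)
  diag(d) <- 0
  new_distance_matrix(d, ids, "jaccard")
}

#' Geographic distance between samples
#'
#' Great-circle (haversine) distance in metres from latitude/longitude on a
#' sphere of radius 6371 km, or plain Euclidean distance for projected
#' coordinates (`planar = TRUE`).
#'
#' @param coordinates Matrix or data frame with one row per sample and two
#'   columns: latitude, longitude in decimal degrees (or x, y when
#'   `planar = TRUE`). Row names become sample ids.
#' @param planar Use Euclidean distance on the raw coordinates.
#' @return Square symmetric `distance_matrix` with
#'   `metric = "geographic"`.
#' @export
geographic_distance <- function(coordinates, planar = FALSE) {
  xy <- as.matrix(coordinates)
  if (ncol(xy) != 2) stop2("coordinates must have two columns")
  if (anyNA(xy)) stop2("missing coordinate in row(s): ",
                       paste(which(rowSums(is.na(xy)) > 0), collapse = ", "))
  ids <- rownames(xy) %||% sprintf("sample_%d", seq_len(nrow(xy)))
  if (planar) {
    d <- as.matrix(stats::dist(xy))
  } else {
    r_earth <- 6371000
    lat <- xy[, 1] * pi / 180
    lon <- xy[, 2] * pi / 180
    dlat <- outer(lat, lat, `-`)
    dlon <- outer(lon, lon, `-`)
    h <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
    h <- pmin(pmax(h, 0), 1)
    d <- 2 * r_earth * asin(sqrt(h))
  }
  diag(d) <- 0
  new_distance_matrix(d, ids, "geographic")
}

# Lower-triangle unfold of a square distance matrix, sample order `ids`
# (NULL keeps the matrix's own order).
unfold_lower <- function(d, ids = NULL) {
  d <- as.matrix(d)
  if (!is.null(ids) && !is.null(rownames(d))) {
    if (!all(ids %in% rownames(d)))
      stop2("distance matrix is missing samples: ",
            paste(setdiff(ids, rownames(d)), collapse = ", "))
    d <- d[ids, ids]
  }
  d[lower.tri(d)]
}

#' Multiple regression on distance matrices
#'
#' Regresses the unfolded lower triangle of a response distance matrix on
#' those of one or more predictor matrices, with significance from a
#' Mantel-type permutation test: the rows and columns of the response matrix
#' are permuted jointly and the model refit; p-values use the add-one
#' correction `p = (1 + #{|b_perm| >= |b_obs|}) / (1 + n_permutations)`,
#' and the overall p compares permuted R-squared values the same way.
#'
#' By default the unfolded distances are z-scored before fitting so
#' coefficients are comparable across predictors; set
#' `standardize = FALSE` for raw-scale coefficients.
#'
#' @param response A `distance_matrix` (or square matrix).
#' @param predictors Named list of `distance_matrix` objects over the same
#'   samples.
#' @param n_permutations Number of permutations (default 999; 0 gives
#'   `NA` p-values, flagged).
#' @param seed Integer seed.
#' @param standardize Z-score the unfolded triangles before fitting.
#' @return List of class `mrm_result`: `coefficients` (data.frame
#'   `predictor`, `coefficient`, `p_value`), `r_squared`, `overall_p`,
#'   `n_permutations`, `seed`.
#' @export
mrm <- function(response, predictors, n_permutations = 999L, seed = 1L,
                standardize = TRUE) {
  if (inherits(predictors, "matrix")) predictors <- list(predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- sprintf("predictor_%d", seq_along(predictors))
  rm_mat <- as.matrix(response)
  n <- nrow(rm_mat)
  if (n < 3) stop2("need at least 3 samples")
  ids <- rownames(rm_mat) %||% as.character(seq_len(n))
  rownames(rm_mat) <- colnames(rm_mat) <- ids
  xs <- lapply(predictors, unfold_lower, ids = ids)
  x <- do.call(cbind, xs)
  if (ncol(x) > 1) {
    r <- stats::cor(x)
    bad <- which(abs(r) > 0.99 & upper.tri(r), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop2("collinear predictor pair: ",
            names(predictors)[bad[1, 1]], " and ",
            names(predictors)[bad[1, 2]])
  }
  zfun <- if (standardize) function(v) as.numeric(scale(v)) else identity
  x <- apply(x, 2, zfun)
  fit_one <- function(yv) {
    f <- stats::lm.fit(cbind(1, x), yv)
    b <- f$coefficients[-1]
    r2 <- 1 - sum(f$residuals^2) / sum((yv - mean(yv))^2)
    list(b = b, r2 = r2)
  }
  y <- zfun(unfold_lower(rm_mat, ids))
  obs <- fit_one(y)
  if (n_permutations > 0) {
    perm <- with_seed(seed, {
      replicate(n_permutations, {
        p <- sample.int(n)
        fit_one(zfun(unfold_lower(rm_mat[p, p], ids = NULL)))
      }, simplify = FALSE)
    })
    bp <- do.call(rbind, lapply(perm, `[[`, "b"))
    r2p <- vapply(perm, `[[`, 0, "r2")
    p_coef <- (1 + colSums(abs(bp) >= matrix(abs(obs$b), n_permutations,
                                             length(obs$b), byrow = TRUE))) /
      (1 + n_permutations)
    p_all <- (1 + sum(r2p >= obs$r2)) / (1 + n_permutations)
  } else {
    warn2("n_permutations = 0: p-values undefined")
    p_coef <- rep(NA_real_, length(obs$b))
    p_all <- NA_real_
  }
  structure(
    list(coefficients = data.frame(predictor = names(predictors),
                                   coefficient = unname(obs$b),
                                   p_value = unname(p_coef),
                                   stringsAsFactors = FALSE),
         r_squared = obs$r2, overall_p = p_all,
         n_permutations = n_permutations, seed = seed,
         standardized = standardize),
    class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("<mrm_result> R2=%.4f overall p=%s (%d permutations)\n",
              x$r_squared,
              if (is.na(x$overall_p)) "NA" else sprintf("%.4g", x$overall_p),
              x$n_permutations))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
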