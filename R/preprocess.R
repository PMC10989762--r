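#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`,
#' the usual normalisation before co-occurrence analysis (subsampling to the
#' minimum reads per sample when `depth = NULL`).
#'
#' @param table A [count_table].
#' @param depth Target depth; defaults to the minimum column sum.
#' @param seed Integer seed.
#' @return A [count_table] whose columns all sum to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  depth <- depth %||% min(totals)
  if (!is_count(depth) || depth < 1) stop2("depth must be a positive integer")
  short <- totals < depth
  if (any(short))
    stop2("depth ", depth, " exceeds reads in sample(s): ",
          paste(colnames(table$counts)[short], collapse = ", "))
  # per-column randomness keyed on the sample id, so the result is invariant
  # to column order under a fixed seed
  id_hash <- function(id) sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 65536L
  out <- vapply(colnames(table$counts), function(sid) {
    x <- table$counts[, sid]
    if (sum(x) == depth) return(as.integer(x))
    with_seed(as.integer(seed) + id_hash(sid), {
      picked <- sample(rep.int(seq_along(x), x), depth, replace = FALSE)
      tabulate(picked, nbins = length(x))
    })
  }, integer(nrow(table$counts)))
  out <- matrix(out, nrow = nrow(table$counts))
  dimnames(out) <- dimnames(table$counts)
  count_table(out, kingdom = table$labels$kingdom,
              guild = table$labels$guild)
}

#' Remove rare taxa by prevalence
#'
#' Drops taxa observed (nonzero count) in fewer than `min_samples` samples,
#' keeping taxon order.
#'
#' @param table A [count_table].
#' @param min_samples Minimum number of samples a taxon must occur in
#'   (default 5).
#' @return A filtered [count_table]; an empty result is allowed and warned
#'   about.
#' @export
prevalence_filter <- function(table, min_samples = 5L) {
  stopifnot(inherits(table, "count_table"))
  if (!is_count(min_samples) || min_samples < 1)
    stop2("min_samples must be >= 1")
  keep <- rowSums(table$counts > 0) >= min_samples
  if (!any(keep)) warn2("prevalence filter removed every taxon")
  count_table(table$counts[keep, , drop = FALSE],
              kingdom = table$labels$kingdom[keep],
              guild = table$labels$guild[keep])
}

#' Merge per-kingdom tables into one multi-kingdom table
#'
#' Aligns blocks to a common sample order (that of the first table) and
#' stacks them. A binary plant presence/absence matrix may be appended as an
#' additional block labelled `"plants"`.
#'
#' @param tables List of [count_table] objects, one per kingdom; kingdom
#'   names within each table must be homogeneous and unique across tables.
#' @param plant_table Optional binary species x samples matrix (0/1).
#' @return A `multi_kingdom_table` (see [multi_kingdom_table]).
#' @export
merge_kingdoms <- function(tables, plant_table = NULL) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, TRUE,
                                            "count_table")))
  kingdoms <- vapply(tables, function(t) unique(t$labels$kingdom)[1], "")
  if (anyDuplicated(kingdoms))
    stop2("duplicate kingdom name: ",
          paste(kingdoms[duplicated(kingdoms)], collapse = ", "))
  ref <- sample_ids(tables[[1]])
  blocks <- lapply(tables, function(t) {
    ids <- sample_ids(t)
    if (!setequal(ids, ref))
      stop2("sample mismatch between kingdoms: ",
            paste(union(setdiff(ids, ref), setdiff(ref, ids)),
                  collapse = ", "))
    count_table(t$counts[, ref, drop = FALSE],
                kingdom = t$labels$kingdom, guild = t$labels$guild)
  })
  names(blocks) <- kingdoms
  if (!is.null(plant_table)) {
    plant_table <- as.matrix(plant_table)
    if (!all(plant_table %in% c(0, 1)))
      stop2("plant_table must be binary (0/1)")
    if ("plants" %in% kingdoms) stop2("duplicate kingdom name: plants")
    ids <- colnames(plant_table)
    if (is.null(ids) || !setequal(ids, ref))
      stop2("sample mismatch between plant table and kingdoms")
    blocks$plants <- count_table(plant_table[, ref, drop = FALSE],
                                 kingdom = "plants")
  }
  structure(list(blocks = blocks, sample_ids = ref),
            class = "multi_kingdom_table")
}

#' Greedy collinearity filter for environmental variables
#'
#' While any variable pair has |Pearson r| above `r_threshold`, drops the
#' member of the worst-offending pair with the larger mean absolute
#' correlation to all other currently retained variables (ties broken by
#' column order). Zero-variance variables are dropped first with a warning.
#'
#' @param env Numeric samples x variables matrix with column names.
#' @param r_threshold Correlation threshold (default 0.7: pairs with
#'   |r| > 0.7 are considered collinear).
#' @return Character vector of retained variable names, with the filtered
#'   matrix in attribute `env`.
#' @export
collinearity_filter <- function(env, r_threshold = 0.7) {
  env <- as.matrix(env)
  if (nrow(env) < 2) stop2("need at least 2 samples")
  if (is.null(colnames(env)))
    colnames(env) <- sprintf("var_%d", seq_len(ncol(env)))
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    warn2("dropping zero-variance variable(s): ",
          paste(colnames(env)[sds == 0], collapse = ", "))
    env <- env[, sds > 0, drop = FALSE]
  }
  keep <- colnames(env)
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(env[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]  # earliest worst pair
    mean_abs <- rowMeans(r)
    a <- min(worst); b <- max(worst)
    # larger mean |r| goes; exact tie -> the later column goes
    drop_idx <- if (mean_abs[a] > mean_abs[b]) a else b
    keep <- keep[-drop_idx]
  }
  structure(keep, env = env[, keep, drop = FALSE])
}
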