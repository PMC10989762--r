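#' Taxon-by-sample count table with kingdom labels
#'
#' The basic container of the package: a non-negative integer matrix with taxa
#' as rows and samples as columns, plus a per-taxon label table giving the
#' kingdom (and, for fungi, an optional functional guild such as
#' ectomycorrhizal or saprotrophic).
#'
#' @param counts Numeric matrix, taxa x samples, non-negative integers.
#'   Row names are taxon identifiers, column names sample identifiers; both
#'   are generated when absent.
#' @param kingdom Character scalar (recycled) or vector of length
#'   `nrow(counts)` naming each taxon's kingdom.
#' @param guild Optional character vector of functional guild labels
#'   (`NA` allowed), length `nrow(counts)`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `labels` (data.frame with columns `taxon_id`,
#'   `kingdom`, `guild`).
#' @examples
#' ct <- count_table(matrix(rpois(12, 5), 3, 4), kingdom = "fungi")
#' ct
#' @export
count_table <- function(counts, kingdom, guild = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop2("counts must be numeric")
  if (any(!is.finite(counts))) stop2("counts must be finite")
  if (any(counts < 0)) stop2("counts must be non-negative")
  if (any(counts != round(counts))) stop2("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon_%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate taxon ids: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate sample ids")
  kingdom <- as.character(kingdom)
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(counts))
  if (length(kingdom) != nrow(counts))
    stop2("kingdom must have one entry per taxon")
  if (anyNA(kingdom)) stop2("kingdom labels must not be NA")
  if (is.null(guild)) guild <- rep(NA_character_, nrow(counts))
  if (length(guild) != nrow(counts))
    stop2("guild must have one entry per taxon")
  structure(
    list(counts = counts,
         labels = data.frame(taxon_id = rownames(counts),
                             kingdom = kingdom,
                             guild = as.character(guild),
                             stringsAsFactors = FALSE)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$labels$kingdom)
  cat("  kingdoms:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

n_taxa <- function(x) nrow(x$counts)
n_samples <- function(x) ncol(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Multi-kingdom table
#'
#' An ordered collection of [count_table] blocks (one per kingdom, optionally
#' including a binary plant presence/absence block) sharing one sample order.
#' This is the object the cross-domain network inference consumes: the
#' centred log-ratio transform is applied per block before concatenation.
#'
#' Built with [merge_kingdoms()].
#'
#' @param x Object to test or print.
#' @name multi_kingdom_table
NULL

#' @export
print.multi_kingdom_table <- function(x, ...) {
  cat(sprintf("<multi_kingdom_table> %d blocks, %d taxa, %d samples\n",
              length(x$blocks), sum(vapply(x$blocks, n_taxa, 1L)),
              length(x$sample_ids)))
  for (nm in names(x$blocks))
    cat(sprintf("  %s: %d taxa\n", nm, n_taxa(x$blocks[[nm]])))
  invisible(x)
}

# Combined label table across blocks.
mk_labels <- function(x) {
  do.call(rbind, lapply(unname(x$blocks), function(b) b$labels))
}

# Combined count matrix (taxa x samples), blocks stacked in order.
mk_counts <- function(x) {
  do.call(rbind, lapply(unname(x$blocks), function(b) b$counts))
}
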