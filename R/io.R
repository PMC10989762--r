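# Plain-text file formats: tab-separated count tables with a sidecar label
# table, signed edge lists, GraphML networks, square distance matrices.

#' Read a taxon-by-sample count table
#'
#' The dialect is a tab-separated file with a header row of sample ids and a
#' leading taxon-id column; an optional sidecar label table (tab-separated:
#' `taxon_id`, `kingdom`, `guild`) supplies taxon annotations. Errors carry
#' line numbers.
#'
#' @param path Path to the count TSV.
#' @param labels_path Optional path to the sidecar label table; when absent,
#'   `kingdom` must be given.
#' @param kingdom Fallback kingdom label when no sidecar table is supplied.
#' @return A [count_table].
#' @export
read_count_table <- function(path, labels_path = NULL, kingdom = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop2(path, ": need a header and at least one taxon")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  samples <- header[-1]
  rows <- cells[-1]
  widths <- lengths(rows)
  if (any(widths != n_col))
    stop2(path, ": ragged row at line ",
          paste(which(widths != n_col)[1] + 1L, collapse = ", "),
          " (expected ", n_col, " fields, found ",
          widths[widths != n_col][1], ")")
  taxa <- vapply(rows, `[`, "", 1)
  if (anyDuplicated(taxa))
    stop2(path, ": duplicate taxon id '", taxa[duplicated(taxa)][1],
          "' at line ", which(duplicated(taxa))[1] + 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(n_col - 1L)))
  vals <- matrix(vals, nrow = n_col - 1L)
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop2(path, ": invalid count at line ", bad[1, 2] + 1L, ", sample '",
          samples[bad[1, 1]], "'")
  counts <- t(vals)
  dimnames(counts) <- list(taxa, samples)
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    need <- c("taxon_id", "kingdom")
    if (!all(need %in% names(lab)))
      stop2(labels_path, ": needs columns taxon_id, kingdom")
    missing <- setdiff(taxa, lab$taxon_id)
    if (length(missing) > 0)
      stop2(labels_path, ": missing labels for ",
            paste(utils::head(missing, 5), collapse = ", "))
    lab <- lab[match(taxa, lab$taxon_id), ]
    return(count_table(counts, kingdom = lab$kingdom,
                       guild = lab$guild %||% NULL))
  }
  if (is.null(kingdom))
    stop2("either labels_path or kingdom must be supplied")
  count_table(counts, kingdom = kingdom)
}

#' Write a count table (and optional sidecar labels)
#'
#' @param table A [count_table].
#' @param path Output TSV path.
#' @param labels_path Optional path for the sidecar label table.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, labels_path = NULL) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path))
    utils::write.table(table$labels, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Write a signed network to file
#'
#' GraphML keeps node attributes (`kingdom`, `guild`) and edge attributes
#' (`sign`, `weight`) and round-trips through common graph viewers; the edge
#' CSV has columns `source`, `target`, `sign`, `weight`.
#'
#' @param net A `signed_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  g <- as_sn_graph(net)
  if (format == "graphml") {
    guild <- igraph::vertex_attr(g, "guild")
    if (!is.null(guild)) {
      guild[is.na(guild)] <- ""
      g <- igraph::set_vertex_attr(g, "guild", value = guild)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     sign = igraph::edge_attr(g, "sign"),
                     weight = igraph::edge_attr(g, "weight") %||%
                       rep(NA_real_, nrow(el)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return A `signed_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    guild <- igraph::vertex_attr(g, "guild")
    if (!is.null(guild)) {
      guild[guild == ""] <- NA_character_
      g <- igraph::set_vertex_attr(g, "guild", value = guild)
    }
    return(signed_network(igraph::as_undirected(g, mode = "each")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  signed_network(g)
}

#' Write a square distance matrix as CSV with sample-id headers
#'
#' @param d A `distance_matrix` (or square matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(data.frame(sample_id = rownames(m), m,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
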