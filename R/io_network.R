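#' Export a connectivity network for external viewers
#'
#' Three formats cover the usual Cytoscape import routes:
#' \describe{
#'   \item{tsv}{edge list with columns `source`, `target`, `rho`,
#'     `q_value`, `sign` (pos/neg); isolated nodes are not listed.}
#'   \item{graphml}{GraphML with the same attributes on edges; the full
#'     node set, including isolated nodes, is preserved.}
#'   \item{sif}{simple interaction format, relation `pos` or `neg`.}
#' }
#'
#' @param network a `connectivity_network`.
#' @param path output file.
#' @param format one of `"tsv"`, `"graphml"`, `"sif"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml", "sif")) {
  stopifnot(inherits(network, "connectivity_network"))
  if (length(format) == 1 && !format %in% c("tsv", "graphml", "sif"))
    mc_stop("unknown format '", format,
            "'; valid formats: tsv, graphml, sif")
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    df <- data.frame(source = e$u, target = e$v,
                     rho = e$rho, q_value = e$q, sign = e$sign,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e)) paste(e$u, e$sign, e$v, sep = "\t") else character()
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("u", "v"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = network$nodes))
    if (nrow(e)) {
      igraph::E(g)$rho <- e$rho
      igraph::E(g)$q_value <- e$q
      igraph::E(g)$sign <- e$sign
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge-list TSV back into a connectivity network
#'
#' Counterpart of `write_network(..., format = "tsv")`, used to feed
#' previously exported networks into [compare_networks()] or
#' [find_modules()].
#'
#' @param path edge-list TSV (`source`, `target`, `rho`, `q_value`,
#'   `sign`).
#' @param condition condition label to attach.
#' @param threshold,fdr provenance to attach (as recorded when written).
#' @return A `connectivity_network`.
#' @export
read_network <- function(path, condition = "unknown", threshold = 0.6,
                         fdr = 0.05) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("source", "target", "rho", "q_value", "sign")
  if (!all(req %in% names(df)))
    mc_stop("edge list in ", path, " must have columns: ",
            paste(req, collapse = ", "))
  edges <- data.frame(u = df$source, v = df$target, rho = df$rho,
                      q = df$q_value, sign = df$sign,
                      stringsAsFactors = FALSE)
  structure(list(condition = condition,
                 nodes = sort(unique(c(edges$u, edges$v))),
                 edges = edges, threshold = threshold, fdr = fdr),
            class = "connectivity_network")
}

#' Count network edges by pathway pair
#'
#' Builds the pathway x pathway contingency matrix of edge counts a Circos
#' table viewer consumes: entry (i, j) is the number of network edges with
#' one endpoint in pathway i and the other in pathway j. Edges within a
#' pathway land on the diagonal. A metabolite in several pathways
#' contributes to each of them; the trait node (if present) is counted
#' under pathway "trait".
#'
#' @param network a `connectivity_network`.
#' @param members_by_pathway named list pathway -> member metabolites.
#' @return Symmetric integer matrix with pathway dimnames.
#' @export
pathway_edge_counts <- function(network, members_by_pathway) {
  stopifnot(inherits(network, "connectivity_network"))
  pw_of <- function(m) {
    hits <- names(members_by_pathway)[vapply(members_by_pathway,
                                             function(v) m %in% v,
                                             logical(1))]
    if (!length(hits)) if (m == "trait") "trait" else "unassigned" else hits
  }
  pws <- sort(unique(c(unlist(lapply(
    unique(c(network$edges$u, network$edges$v)), pw_of)),
    names(members_by_pathway))))
  M <- matrix(0L, length(pws), length(pws), dimnames = list(pws, pws))
  e <- network$edges
  for (k in seq_len(nrow(e))) {
    for (pu in pw_of(e$u[k])) for (pv in pw_of(e$v[k])) {
      M[pu, pv] <- M[pu, pv] + 1L
      if (pu != pv) M[pv, pu] <- M[pv, pu] + 1L
    }
  }
  M
}

#' Write a pathway contingency table in Circos tableviewer layout
#'
#' Plain-text layout the Circos `tableviewer` tool parses: a header row of
#' column labels and one labelled row of counts per pathway.
#'
#' @param counts square non-negative integer matrix with identical row and
#'   column labels.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_circos_table <- function(counts, path) {
  if (!is.matrix(counts) || nrow(counts) == 0)
    mc_stop("counts must be a non-empty matrix (nothing to plot)")
  if (nrow(counts) != ncol(counts))
    mc_stop("counts must be square (got ", nrow(counts), " x ",
            ncol(counts), ")")
  if (any(counts < 0) || any(counts != round(counts)))
    mc_stop("counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    mc_stop("counts must carry pathway labels as dimnames")
  lines <- c(paste(c("labels", colnames(counts)), collapse = "\t"),
             vapply(seq_len(nrow(counts)), function(i)
               paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
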