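#' Distance-k power graph of a pathway graph
#'
#' Two nodes are adjacent in the result iff their shortest-path distance in
#' the input graph is positive and at most `k`. Nodes in different
#' components are never connected. This is the standard realisation of the
#' "pairwise distance at most k" criterion used by the k-clique subpathway
#' method: subpathways are exactly the maximal cliques of this graph.
#'
#' @param g a [pathway_graph].
#' @param k positive integer distance bound.
#' @return an igraph object over the same (sorted) node set.
#' @export
distance_power_graph <- function(g, k) {
  stopifnot(inherits(g, "pathway_graph"), k >= 1)
  ig <- as_igraph(g)
  d <- igraph::distances(ig)
  adj <- is.finite(d) & d > 0 & d <= k
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Mine k-clique subpathways of one pathway
#'
#' A subpathway is a maximal set of pathway nodes whose pairwise graph
#' distance is at most `k`; equivalently a maximal clique of
#' [distance_power_graph]. Enumeration order is deterministic
#' (lexicographic by sorted node list) and subpathway ids are assigned in
#' that order as `"<pathway_id>_<n>"` with 1-based `n`.
#'
#' @param g a [pathway_graph].
#' @param k positive integer distance bound (3 in the reference analysis).
#' @param min_size minimum number of nodes per subpathway (default 2;
#'   singletons carry no interaction information).
#' @return list of `subpathway` objects, each a list with fields
#'   `subpathway_id`, `pathway_id`, `nodes`, `genes`.
#' @export
mine_subpathways <- function(g, k = 3, min_size = 2) {
  stopifnot(inherits(g, "pathway_graph"), k >= 1, min_size >= 1)
  pg <- distance_power_graph(g, k)
  cl <- igraph::max_cliques(pg, min = min_size)
  node_sets <- lapply(cl, function(v) sort(igraph::V(pg)$name[v]))
  if (length(node_sets) == 0L) return(list())
  keys <- vapply(node_sets, paste, "", collapse = "\r")
  node_sets <- node_sets[order(keys)]
  lapply(seq_along(node_sets), function(i) {
    nodes <- node_sets[[i]]
    structure(
      list(subpathway_id = sprintf("%s_%d", g$pathway_id, i),
           pathway_id = g$pathway_id,
           nodes = nodes,
           genes = sort(unique(unlist(g$node_genes[nodes], use.names = FALSE)))),
      class = "subpathway")
  })
}

#' Mine subpathways across a pathway collection
#'
#' @param pathways list of [pathway_graph] objects with unique pathway ids.
#' @param k,min_size passed to [mine_subpathways].
#' @return named list (the subpathway catalog): subpathway id ->
#'   `subpathway` object; ids are globally unique.
#' @export
mine_all <- function(pathways, k = 3, min_size = 2) {
  pids <- vapply(pathways, function(p) p$pathway_id, "")
  if (anyDuplicated(pids)) {
    stop("duplicate pathway_id: ", paste(unique(pids[duplicated(pids)]), collapse = ", "))
  }
  sps <- unlist(lapply(pathways, mine_subpathways, k = k, min_size = min_size),
                recursive = FALSE)
  if (length(sps) == 0L) return(stats::setNames(list(), character(0)))
  stats::setNames(sps, vapply(sps, function(s) s$subpathway_id, ""))
}

#' Read/write a subpathway catalog TSV
#'
#' Columns: `subpathway_id`, `pathway_id`, `nodes` (semicolon list),
#' `genes` (semicolon list).
#' @param catalog named list of subpathways, as from [mine_all].
#' @param path file path.
#' @return `write_catalog`: `path` invisibly; `read_catalog`: the catalog.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(
    subpathway_id = vapply(catalog, function(s) s$subpathway_id, ""),
    pathway_id = vapply(catalog, function(s) s$pathway_id, ""),
    nodes = vapply(catalog, function(s) paste(s$nodes, collapse = ";"), ""),
    genes = vapply(catalog, function(s) paste(s$genes, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  sps <- lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(subpathway_id = df$subpathway_id[[i]],
           pathway_id = df$pathway_id[[i]],
           nodes = sort(strsplit(df$nodes[[i]], ";", fixed = TRUE)[[1L]]),
           genes = sort(strsplit(df$genes[[i]], ";", fixed = TRUE)[[1L]])),
      class = "subpathway")
  })
  stats::setNames(sps, df$subpathway_id)
}

#' Gene sets of a catalog
#' @param catalog a subpathway catalog.
#' @return named list: subpathway id -> character vector of gene ids.
#' @export
catalog_gene_sets <- function(catalog) {
  lapply(catalog, function(s) s$genes)
}
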