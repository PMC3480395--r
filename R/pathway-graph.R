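#' Construct a pathway graph
#'
#' A pathway graph is the undirected enzyme/gene graph of one metabolic
#' pathway. Nodes are enzyme-level entities; each node is annotated with a
#' non-empty set of gene identifiers (a single enzyme node may map to
#' several genes). Edges are unordered and self-loops are disallowed; the
#' graph may be disconnected.
#'
#' @param pathway_id single string, e.g. `"path:00790"`.
#' @param name human-readable pathway name.
#' @param nodes character vector of node identifiers.
#' @param edges two-column character matrix (or data.frame) of unordered
#'   node-id pairs; may have zero rows.
#' @param node_genes named list mapping every node id to a non-empty
#'   character vector of gene ids.
#' @return An object of class `pathway_graph` with normalised (sorted)
#'   nodes, edges and gene annotations.
#' @export
pathway_graph <- function(pathway_id, name, nodes, edges, node_genes) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            is.character(name), length(name) == 1L)
  nodes <- sort(unique(as.character(nodes)))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed in a pathway graph")
  }
  missing_ep <- setdiff(unique(c(edges)), nodes)
  if (length(missing_ep) > 0L) {
    stop("edge references unknown node(s): ", paste(missing_ep, collapse = ", "))
  }
  # canonical edge order: within-pair sorted, then row-sorted, deduplicated
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  colnames(edges) <- c("from", "to")

  node_genes <- lapply(node_genes, function(g) sort(unique(as.character(g))))
  uncovered <- setdiff(nodes, names(node_genes))
  if (length(uncovered) > 0L) {
    stop("node(s) without gene annotation: ", paste(uncovered, collapse = ", "))
  }
  if (any(lengths(node_genes[nodes]) == 0L)) {
    stop("every node needs a non-empty gene set")
  }
  structure(
    list(pathway_id = pathway_id, name = name, nodes = nodes,
         edges = edges, node_genes = node_genes[nodes]),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s (%s): %d nodes, %d edges, %d genes\n",
              x$pathway_id, x$name, length(x$nodes), nrow(x$edges),
              length(unique(unlist(x$node_genes)))))
  invisible(x)
}

#' All genes annotated to a pathway graph
#' @param g a `pathway_graph`.
#' @return sorted character vector of gene ids.
#' @export
pathway_genes <- function(g) sort(unique(unlist(g$node_genes, use.names = FALSE)))

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Read a pathway graph from disk
#'
#' Two plain-text dialects are supported. `"edgelist-tsv"` is a TSV with a
#' header line `#<pathway_id>\t<name>` followed by
#' `NODE\t<id>\t<gene1;gene2;...>` and `EDGE\t<id_a>\t<id_b>` rows.
#' `"kgml-subset"` is a reduced KGML: only `<entry>` elements of type
#' `enzyme` or `gene` (genes taken from the whitespace/semicolon-separated
#' `name` attribute) and `<relation entry1= entry2=>` connectivity are
#' honoured; relations are collapsed to undirected edges because the
#' downstream distance criterion is undirected.
#'
#' @param path file path.
#' @param format `"edgelist-tsv"` (default) or `"kgml-subset"`.
#' @return a validated [pathway_graph].
#' @export
read_pathway <- function(path, format = c("edgelist-tsv", "kgml-subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edgelist-tsv") read_pathway_edgelist(path) else read_pathway_kgml(path)
}

read_pathway_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#")) {
    stop("malformed pathway edgelist ", path,
         ": first line must be '#<pathway_id>\\t<name>'")
  }
  hdr <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L) stop("malformed header line in ", path)
  nodes <- character(0); node_genes <- list()
  edges <- matrix(character(0), ncol = 2L)
  for (i in seq_along(lines)[-1L]) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (f[[1L]] == "NODE") {
      if (!length(f) %in% 2:3) stop("malformed NODE row at line ", i, " of ", path)
      genes <- if (length(f) == 3L) strsplit(f[[3L]], ";", fixed = TRUE)[[1L]]
               else character(0)
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) stop("node '", f[[2L]], "' has no genes (line ", i, ")")
      nodes <- c(nodes, f[[2L]])
      node_genes[[f[[2L]]]] <- genes
    } else if (f[[1L]] == "EDGE") {
      if (length(f) != 3L) stop("malformed EDGE row at line ", i, " of ", path)
      edges <- rbind(edges, f[2:3])
    } else {
      stop("unknown row type '", f[[1L]], "' at line ", i, " of ", path)
    }
  }
  pathway_graph(hdr[[1L]], hdr[[2L]], nodes, edges, node_genes)
}

read_pathway_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed KGML in ", path, ": ",
                                           conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("KGML file ", path, " lacks a <pathway> root element")
  pid <- xml2::xml_attr(root, "name")
  nm <- xml2::xml_attr(root, "title")
  if (is.na(nm)) nm <- pid
  entries <- xml2::xml_find_all(doc, "//entry[@type='enzyme' or @type='gene']")
  nodes <- xml2::xml_attr(entries, "id")
  gene_attr <- xml2::xml_attr(entries, "name")
  node_genes <- lapply(gene_attr, function(s) {
    g <- strsplit(s, "[;[:space:]]+")[[1L]]
    g[nzchar(g)]
  })
  names(node_genes) <- nodes
  rels <- xml2::xml_find_all(doc, "//relation")
  edges <- cbind(xml2::xml_attr(rels, "entry1"), xml2::xml_attr(rels, "entry2"))
  # keep only relations between retained (enzyme/gene) entries
  keep <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
  pathway_graph(pid, nm, nodes, edges[keep, , drop = FALSE], node_genes)
}

#' Write a pathway graph in the edgelist-tsv dialect
#' @param g a `pathway_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", g$pathway_id, "\t", g$name), con)
  for (n in g$nodes) {
    writeLines(paste("NODE", n, paste(g$node_genes[[n]], collapse = ";"),
                     sep = "\t"), con)
  }
  if (nrow(g$edges) > 0L) {
    writeLines(paste("EDGE", g$edges[, 1L], g$edges[, 2L], sep = "\t"), con)
  }
  invisible(path)
}
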