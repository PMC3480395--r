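# Small in-code fixtures and independent oracles shared across tests.

# pathway graph from an edge list given as c("A-B", "B-C", ...); every node
# gets one gene named g<node> unless `genes` overrides it
toy_pathway <- function(id, edges, nodes = NULL, genes = NULL) {
  pairs <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
  if (is.null(nodes)) nodes <- sort(unique(c(pairs)))
  if (is.null(genes)) {
    genes <- lapply(nodes, function(n) paste0("g", n))
    names(genes) <- nodes
  }
  pathway_graph(id, paste0("toy ", id), nodes,
                if (length(edges)) pairs else matrix(character(0), ncol = 2),
                genes)
}

# drsn straight from an edge list of c(drug, subpathway) pairs
toy_drsn <- function(..., alpha = 0.01) {
  e <- do.call(rbind, list(...))
  drsn(data.frame(drug_id = e[, 1], subpathway_id = e[, 2],
                  p_value = 1e-4, stringsAsFactors = FALSE), alpha)
}

# minimal catalog entry without mining
toy_subpathway <- function(id, genes, pathway_id = "path:toy") {
  structure(list(subpathway_id = id, pathway_id = pathway_id,
                 nodes = genes, genes = sort(unique(genes))),
            class = "subpathway")
}

toy_catalog <- function(gene_sets) {
  stats::setNames(lapply(names(gene_sets), function(id)
    toy_subpathway(id, gene_sets[[id]])), names(gene_sets))
}

# ---- independent oracles ------------------------------------------------

# all-pairs shortest path by plain BFS, independent of igraph
bfs_distances <- function(nodes, edge_mat) {
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (length(edge_mat)) {
    for (r in seq_len(nrow(edge_mat))) {
      i <- match(edge_mat[r, 1], nodes); j <- match(edge_mat[r, 2], nodes)
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# brute-force k-clique subpathway enumeration: all subsets with pairwise
# distance <= k, kept if maximal and at least min_size nodes
brute_force_subpathways <- function(g, k, min_size = 2) {
  d <- bfs_distances(g$nodes, g$edges)
  n <- length(g$nodes)
  feasible <- function(idx) all(d[idx, idx] <= k)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(idx) < min_size || !feasible(idx)) next
    rest <- setdiff(seq_len(n), idx)
    maximal <- !any(vapply(rest, function(v) all(d[v, idx] <= k), TRUE))
    if (maximal) out[[length(out) + 1L]] <- sort(g$nodes[idx])
  }
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

random_toy_pathway <- function(id, n, p_edge = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- t(pairs[, keep, drop = FALSE])
  genes <- stats::setNames(lapply(nodes, function(x) paste0("g", x)), nodes)
  pathway_graph(id, "random toy", nodes,
                if (nrow(edges)) edges else matrix(character(0), ncol = 2),
                genes)
}

node_set_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), ""))
}
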