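drsn_igraph <- function(net) {
  # drug and subpathway id namespaces may collide in pathological inputs;
  # prefix the two sides to keep the graph honestly bipartite
  e <- data.frame(from = paste0("drug::", net$edges$drug_id),
                  to = paste0("sp::", net$edges$subpathway_id),
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = FALSE)
}

#' Descriptive statistics of a DRSN
#'
#' Node counts per side, edge count, size of the giant (largest connected)
#' component of the bipartite graph taken as undirected, and the full
#' degree sequence of each side with its extremes.
#'
#' @param net a [drsn].
#' @return list with `n_drugs`, `n_subpathways`, `n_nodes`, `n_edges`,
#'   `giant_component_size`, `drug_degrees` and `subpathway_degrees`
#'   (named integer vectors), and `max_drug_degree`, `min_drug_degree`,
#'   `max_subpathway_degree`, `min_subpathway_degree`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "drsn"))
  dd <- table(factor(net$edges$drug_id, levels = net$drug_nodes))
  sd_ <- table(factor(net$edges$subpathway_id, levels = net$subpathway_nodes))
  drug_degrees <- stats::setNames(as.integer(dd), names(dd))
  sp_degrees <- stats::setNames(as.integer(sd_), names(sd_))
  giant <- if (nrow(net$edges) == 0L) 0L else {
    max(igraph::components(drsn_igraph(net))$csize)
  }
  list(n_drugs = length(net$drug_nodes),
       n_subpathways = length(net$subpathway_nodes),
       n_nodes = length(net$drug_nodes) + length(net$subpathway_nodes),
       n_edges = nrow(net$edges),
       giant_component_size = as.integer(giant),
       drug_degrees = drug_degrees,
       subpathway_degrees = sp_degrees,
       max_drug_degree = if (length(drug_degrees)) max(drug_degrees) else 0L,
       min_drug_degree = if (length(drug_degrees)) min(drug_degrees) else 0L,
       max_subpathway_degree = if (length(sp_degrees)) max(sp_degrees) else 0L,
       min_subpathway_degree = if (length(sp_degrees)) min(sp_degrees) else 0L)
}

#' Log-log least-squares fit of a degree distribution
#'
#' Fits an ordinary least-squares line through (log10 k, log10 P(k)) over
#' the observed degrees k, where P(k) is the fraction of nodes with degree
#' exactly k. This is the conventional quick check that a degree
#' distribution is approximately power-law (scale-free); it is descriptive,
#' not a formal power-law test.
#'
#' @param degree_sequence integer vector of node degrees (one per node).
#' @return list with `slope` and `r_squared`.
#' @export
powerlaw_fit <- function(degree_sequence) {
  degree_sequence <- degree_sequence[degree_sequence > 0]
  tab <- table(degree_sequence)
  if (length(tab) < 3L) {
    stop("powerlaw_fit needs at least 3 distinct positive degree values")
  }
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(degree_sequence)
  fit <- stats::lm(log10(pk) ~ log10(k))
  list(slope = unname(stats::coef(fit)[[2L]]),
       r_squared = summary(fit)$r.squared)
}

#' Degree-preserving shuffle of drug-gene associations
#'
#' Randomises a bipartite drug-gene edge set by repeated edge swaps: pick
#' two edges (d1,g1), (d2,g2) and replace them with (d1,g2), (d2,g1) when
#' neither replacement already exists. Every drug's gene count and every
#' gene's drug count are preserved exactly, which is the null model used to
#' assess whether the DRSN is denser than chance.
#'
#' @param assoc data.frame with columns `drug_id`, `gene_id` (distinct rows).
#' @param n_swaps number of attempted swaps; default 10 edges worth of
#'   mixing per edge (`10 * nrow(assoc)`).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame of the same shape with shuffled associations.
#' @export
randomize_drug_gene <- function(assoc, n_swaps = 10L * nrow(assoc), seed = NULL) {
  stopifnot(is.data.frame(assoc),
            all(c("drug_id", "gene_id") %in% names(assoc)), n_swaps >= 0)
  if (anyDuplicated(assoc[c("drug_id", "gene_id")])) {
    stop("duplicate drug-gene edges")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- assoc$drug_id; g <- assoc$gene_id
  ne <- length(d)
  if (ne < 2L || n_swaps == 0L) return(assoc)
  present <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) paste0(a, "\r", b)
  for (i in seq_len(ne)) assign(key(d[[i]], g[[i]]), TRUE, envir = present)
  picks <- matrix(sample.int(ne, 2L * n_swaps, replace = TRUE), ncol = 2L)
  for (s in seq_len(n_swaps)) {
    i <- picks[s, 1L]; j <- picks[s, 2L]
    if (i == j) next
    di <- d[[i]]; gi <- g[[i]]; dj <- d[[j]]; gj <- g[[j]]
    if (gi == gj || di == dj) next
    k1 <- key(di, gj); k2 <- key(dj, gi)
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(di, gi), key(dj, gj)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    g[[i]] <- gj; g[[j]] <- gi
  }
  out <- data.frame(drug_id = d, gene_id = g, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

drug_sets_to_edges <- function(drug_sets) {
  drug_sets <- drug_sets[lengths(drug_sets) > 0L]
  data.frame(drug_id = rep(names(drug_sets), lengths(drug_sets)),
             gene_id = unlist(drug_sets, use.names = FALSE),
             stringsAsFactors = FALSE)
}

edges_to_drug_sets <- function(edges, all_drugs = NULL) {
  sets <- lapply(split(edges$gene_id, edges$drug_id), sort)
  if (!is.null(all_drugs)) {
    missing <- setdiff(all_drugs, names(sets))
    sets[missing] <- list(character(0))
  }
  sets[sort(names(sets))]
}

#' Compare a DRSN against degree-preserving random networks
#'
#' For each replicate, the observed drug-gene associations are shuffled
#' with [randomize_drug_gene] (both each drug's affected-gene count and
#' each gene's drug count are preserved), enrichment is re-run and a random
#' DRSN is built. Empirical p-values for the observed edge count and the
#' average degree of each side use the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_random)`, so they are bounded away
#' from zero; raw exceedance counts are returned alongside.
#'
#' @param drug_sets named list: drug id -> affected gene ids.
#' @param catalog subpathway catalog.
#' @param background background gene universe.
#' @param alpha edge significance threshold.
#' @param n_random number of random replicates (1000 in the reference
#'   setting; scale down for quick checks).
#' @param seed integer seed.
#' @return list with `observed` (edge count and per-side average degrees),
#'   `null_mean`, `exceedances`, and `empirical_p` for each statistic.
#' @export
null_network_comparison <- function(drug_sets, catalog, background,
                                    alpha = 0.01, n_random = 100L, seed = 1L) {
  stopifnot(n_random >= 1)
  obs <- build_drsn(drug_sets, catalog, background, alpha)$network
  stat_of <- function(net) {
    c(n_edges = nrow(net$edges),
      avg_drug_degree = if (length(net$drug_nodes))
        nrow(net$edges) / length(net$drug_nodes) else 0,
      avg_subpathway_degree = if (length(net$subpathway_nodes))
        nrow(net$edges) / length(net$subpathway_nodes) else 0)
  }
  observed <- stat_of(obs)
  edges <- drug_sets_to_edges(drug_sets)
  set.seed(seed)
  null_stats <- matrix(0, nrow = n_random, ncol = 3L,
                       dimnames = list(NULL, names(observed)))
  for (b in seq_len(n_random)) {
    shuffled <- randomize_drug_gene(edges)
    null_sets <- edges_to_drug_sets(shuffled)
    null_net <- suppressWarnings(
      build_drsn(null_sets, catalog, background, alpha))$network
    null_stats[b, ] <- stat_of(null_net)
  }
  exceed <- colSums(sweep(null_stats, 2L, observed, ">=") * 1)
  list(observed = observed,
       null_mean = colMeans(null_stats),
       exceedances = exceed,
       empirical_p = (1 + exceed) / (1 + n_random),
       n_random = n_random)
}
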