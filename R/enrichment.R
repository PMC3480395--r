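#' Upper-tail hypergeometric probability
#'
#' Exact P(X >= r) for X ~ Hypergeometric(N, m, n): drawing the drug's n
#' background genes from a universe of N genes of which m belong to the
#' subpathway. Computed by explicit term summation in log space
#' (log-binomials via `lchoose`, combined with a log-sum-exp), so the tail
#' is stable even when individual terms underflow.
#'
#' @param overlap observed overlap r.
#' @param drug_n number of drug genes in the background, n.
#' @param subpath_m number of subpathway genes in the background, m.
#' @param background_n background universe size, N.
#' @return probability in (0, 1].
#' @export
hypergeometric_pvalue <- function(overlap, drug_n, subpath_m, background_n) {
  r <- overlap; n <- drug_n; m <- subpath_m; N <- background_n
  if (any(c(r, n, m, N) < 0) || r > min(n, m) || n > N || m > N) {
    stop("inconsistent hypergeometric counts: r=", r, " n=", n,
         " m=", m, " N=", N)
  }
  if (r == 0) return(1)
  x <- r:min(n, m)
  log_terms <- lchoose(m, x) + lchoose(N - m, n - x) - lchoose(N, n)
  mx <- max(log_terms)
  min(1, exp(mx + log(sum(exp(log_terms - mx)))))
}

#' Construct a drug-metabolic subpathway network (DRSN)
#'
#' Low-level constructor; most users should call [build_drsn]. Nodes with
#' degree zero are not represented: every drug and subpathway node carries
#' at least one significant edge.
#'
#' @param edges data.frame with columns `drug_id`, `subpathway_id`,
#'   `p_value`.
#' @param alpha the significance threshold the edges were called at.
#' @return object of class `drsn`.
#' @export
drsn <- function(edges, alpha) {
  stopifnot(is.data.frame(edges),
            all(c("drug_id", "subpathway_id", "p_value") %in% names(edges)))
  edges <- edges[order(edges$drug_id, edges$subpathway_id), , drop = FALSE]
  rownames(edges) <- NULL
  if (anyDuplicated(edges[c("drug_id", "subpathway_id")])) {
    stop("duplicate drug-subpathway edges")
  }
  structure(
    list(drug_nodes = sort(unique(edges$drug_id)),
         subpathway_nodes = sort(unique(edges$subpathway_id)),
         edges = edges, alpha = alpha),
    class = "drsn")
}

#' @export
print.drsn <- function(x, ...) {
  cat(sprintf("<drsn> %d drugs, %d subpathways, %d edges (alpha = %g)\n",
              length(x$drug_nodes), length(x$subpathway_nodes),
              nrow(x$edges), x$alpha))
  invisible(x)
}

#' Build the DRSN by per-pair enrichment testing
#'
#' Every drug's affected-gene set is tested against every subpathway's gene
#' set with an upper-tail hypergeometric test after intersecting both with
#' the background universe; a drug-subpathway edge is drawn iff
#' `p_value < alpha`. Drugs whose gene set is disjoint from the background
#' are skipped with a warning. All tested results are returned for audit.
#'
#' @param drug_sets named list: drug id -> affected gene ids.
#' @param catalog subpathway catalog from [mine_all].
#' @param background character vector of background gene ids (typically the
#'   union of all pathway-annotated genes).
#' @param alpha significance threshold in (0, 1); default 0.01.
#' @return list with elements `network` (a [drsn]) and `results`
#'   (data.frame of all tests: drug_id, subpathway_id, overlap, drug_n,
#'   subpath_m, background_n, p_value).
#' @export
build_drsn <- function(drug_sets, catalog, background, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1, length(background) > 0)
  background <- unique(as.character(background))
  N <- length(background)
  sp_sets <- lapply(catalog_gene_sets(catalog), intersect, background)
  sp_sets <- sp_sets[lengths(sp_sets) > 0L]
  drug_ids <- sort(names(drug_sets))
  res <- vector("list", length(drug_ids))
  for (di in seq_along(drug_ids)) {
    d <- drug_ids[[di]]
    genes <- intersect(drug_sets[[d]], background)
    if (length(genes) == 0L) {
      if (length(drug_sets[[d]]) > 0L) {
        warning("drug '", d, "' has no genes in the background; skipped")
      }
      next
    }
    n <- length(genes)
    ov <- vapply(sp_sets, function(s) length(intersect(genes, s)), 0L)
    m <- lengths(sp_sets)
    p <- vapply(seq_along(sp_sets), function(j) {
      hypergeometric_pvalue(ov[[j]], n, m[[j]], N)
    }, 0)
    res[[di]] <- data.frame(drug_id = d, subpathway_id = names(sp_sets),
                            overlap = unname(ov), drug_n = n,
                            subpath_m = unname(m), background_n = N,
                            p_value = p, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  if (is.null(results)) {
    results <- data.frame(drug_id = character(0), subpathway_id = character(0),
                          overlap = integer(0), drug_n = integer(0),
                          subpath_m = integer(0), background_n = integer(0),
                          p_value = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(results) <- NULL
  # alpha = 1 is the degenerate keep-everything boundary (p_value <= 1 always)
  sig <- results[results$p_value < alpha | alpha >= 1,
                 c("drug_id", "subpathway_id", "p_value"), drop = FALSE]
  list(network = drsn(sig, alpha), results = results)
}

#' Read/write DRSN edge tables
#'
#' Three-column TSV: `drug_id`, `subpathway_id`, `p_value`. This is also
#' the dialect used to ingest externally published drug-subpathway
#' association tables for validation (a missing/blank `p_value` column is
#' read as `NA`).
#'
#' @param net a [drsn] (for writing).
#' @param path file path.
#' @param alpha significance threshold to record on a read network.
#' @return `write_drsn_edges`: `path` invisibly; `read_drsn_edges`: a
#'   [drsn].
#' @export
write_drsn_edges <- function(net, path) {
  stopifnot(inherits(net, "drsn"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_drsn_edges
#' @export
read_drsn_edges <- function(path, alpha = 0.01) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "subpathway_id") %in% names(df))) {
    stop("DRSN edge table needs columns drug_id and subpathway_id")
  }
  if (is.null(df$p_value)) df$p_value <- NA_real_
  drsn(df[c("drug_id", "subpathway_id", "p_value")], alpha)
}

#' Subpathway neighbours per drug
#' @param net a [drsn].
#' @return named list: drug id -> sorted subpathway ids it links to.
#' @export
drug_neighbours <- function(net) {
  lapply(split(net$edges$subpathway_id, net$edges$drug_id), sort)
}

#' Drug neighbours per subpathway
#' @param net a [drsn].
#' @return named list: subpathway id -> sorted drug ids linked to it.
#' @export
subpathway_neighbours <- function(net) {
  lapply(split(net$edges$drug_id, net$edges$subpathway_id), sort)
}
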