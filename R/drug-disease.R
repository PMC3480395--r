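#' Fold enrichment ratio between two subpathway sets
#'
#' FER = O / E with O the observed number of shared subpathways and
#' E = |S_drug| * |S_disease| / U the expected number under independent
#' placement into a union universe of size U. Returns 0 when the sets are
#' disjoint.
#'
#' @param drug_subpaths,disease_subpaths character vectors of subpathway ids.
#' @param union_size the relevant union universe size U (conventionally the
#'   number of distinct subpathways carried by the drug's class or the
#'   disease's class).
#' @return non-negative real.
#' @export
fer <- function(drug_subpaths, disease_subpaths, union_size) {
  drug_subpaths <- unique(drug_subpaths)
  disease_subpaths <- unique(disease_subpaths)
  if (union_size == 0) stop("union_size must be positive")
  if (union_size < max(length(drug_subpaths), length(disease_subpaths))) {
    stop("union_size smaller than one of the subpathway sets")
  }
  O <- length(intersect(drug_subpaths, disease_subpaths))
  if (O == 0L) return(0)
  E <- length(drug_subpaths) * length(disease_subpaths) / union_size
  O / E
}

#' Hypergeometric significance of a drug-disease subpathway overlap
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a drug's and a disease's subpathway sets, with the
#' population being all subpathways mined at the chosen k (743 in the
#' reference analysis at k = 3). Pairs with p < 0.01 are conventionally
#' flagged significant.
#'
#' @param drug_subpaths,disease_subpaths character vectors of subpathway ids.
#' @param population total number of mined subpathways.
#' @return probability in (0, 1].
#' @export
overlap_significance <- function(drug_subpaths, disease_subpaths, population) {
  drug_subpaths <- unique(drug_subpaths)
  disease_subpaths <- unique(disease_subpaths)
  u <- length(union(drug_subpaths, disease_subpaths))
  if (population < u) stop("population smaller than the observed union")
  hypergeometric_pvalue(length(intersect(drug_subpaths, disease_subpaths)),
                        length(drug_subpaths), length(disease_subpaths),
                        population)
}

#' Drug class x disease class association scores
#'
#' For drug class i and disease class j,
#' `AS(i, j) = (1 / (N_i * N_j)) * sum_{s in i} sum_{t in j} FER(s, t)`,
#' where N_i and N_j are the class sizes and each pair-level FER uses as
#' union size the number of distinct subpathways linked to any drug of
#' class i or any disease of class j. Drugs without a class or without
#' subpathways, and likewise diseases, are excluded; empty classes are
#' absent from the result rather than zero rows.
#'
#' @param net a [drsn] supplying drug -> subpathway links.
#' @param tables an [association_tables] supplying `drug_class`,
#'   `disease_subpathways` and `disease_class`.
#' @param population total mined subpathway count used for pair-level
#'   overlap p-values (default: number of distinct subpathways seen across
#'   the network and the disease map).
#' @param significance_alpha threshold for flagging pair results.
#' @return list with `scores` (matrix drug classes x disease classes),
#'   `pair_results` (data.frame: drug_id, disease_id, fer, overlap_p,
#'   significant), `drug_classes`, `disease_classes`.
#' @export
association_scores <- function(net, tables, population = NULL,
                               significance_alpha = 0.01) {
  drug_sp <- drug_neighbours(net)
  dcl <- tables$drug_class
  dcl <- dcl[names(dcl) %in% names(drug_sp)]
  dis_sp <- tables$disease_subpathways
  dis_sp <- dis_sp[lengths(dis_sp) > 0L]
  scl <- tables$disease_class
  scl <- scl[names(scl) %in% names(dis_sp)]
  if (is.null(population)) {
    population <- length(unique(c(unlist(drug_sp, use.names = FALSE),
                                  unlist(dis_sp, use.names = FALSE))))
  }
  drug_classes <- sort(unique(unname(dcl)))
  disease_classes <- sort(unique(unname(scl)))
  scores <- matrix(NA_real_, length(drug_classes), length(disease_classes),
                   dimnames = list(drug_classes, disease_classes))
  pair_rows <- list()
  for (ci in drug_classes) {
    ci_drugs <- names(dcl)[dcl == ci]
    for (cj in disease_classes) {
      cj_dis <- names(scl)[scl == cj]
      u <- length(unique(c(unlist(drug_sp[ci_drugs], use.names = FALSE),
                           unlist(dis_sp[cj_dis], use.names = FALSE))))
      total <- 0
      for (s in ci_drugs) {
        for (t in cj_dis) {
          f <- fer(drug_sp[[s]], dis_sp[[t]], u)
          total <- total + f
          if (f > 0) {
            p <- overlap_significance(drug_sp[[s]], dis_sp[[t]], population)
            pair_rows[[length(pair_rows) + 1L]] <-
              data.frame(drug_id = s, disease_id = t, fer = f, overlap_p = p,
                         significant = p < significance_alpha,
                         stringsAsFactors = FALSE)
          }
        }
      }
      scores[ci, cj] <- total / (length(ci_drugs) * length(cj_dis))
    }
  }
  pair_results <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(drug_id = character(0), disease_id = character(0),
               fer = numeric(0), overlap_p = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  pair_results <- pair_results[order(pair_results$drug_id,
                                     pair_results$disease_id), , drop = FALSE]
  rownames(pair_results) <- NULL
  list(scores = scores, pair_results = pair_results,
       drug_classes = drug_classes, disease_classes = disease_classes)
}
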