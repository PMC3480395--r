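#' Call differentially expressed genes for one instance
#'
#' Fold-change calling on one paired treatment/control profile: gene g is a
#' DEG when `|log2((treatment_g + pseudocount) / (control_g + pseudocount))|`
#' strictly exceeds `log2_threshold`. Down-regulation counts the same as
#' up-regulation. The pseudocount guards zero denominators; with array-scale
#' intensities the distortion is negligible.
#'
#' @param inst an [expression_instance].
#' @param log2_threshold positive log2 fold-change bound (default 1,
#'   i.e. two-fold).
#' @param pseudocount non-negative intensity offset (default 1).
#' @return character vector of DEG gene ids (sorted).
#' @export
call_degs <- function(inst, log2_threshold = 1, pseudocount = 1) {
  stopifnot(inherits(inst, "expression_instance"),
            log2_threshold > 0, pseudocount >= 0)
  ctl <- inst$control + pseudocount
  if (any(ctl == 0)) {
    stop("zero control intensity with pseudocount = 0; supply a positive pseudocount")
  }
  lfc <- log2((inst$treatment + pseudocount) / ctl)
  sort(inst$genes[abs(lfc) > log2_threshold])
}

#' Merge per-instance DEGs into per-drug affected-gene sets
#'
#' DEG sets of all instances belonging to the same drug are unioned; the
#' union is that drug's affected-gene set. Drugs whose union is empty are
#' retained (they are simply never enriched downstream).
#'
#' @param instances list of [expression_instance] objects.
#' @param log2_threshold,pseudocount passed to [call_degs].
#' @return named list: drug id -> sorted character vector of affected genes.
#' @export
merge_drug_genes <- function(instances, log2_threshold = 1, pseudocount = 1) {
  drugs <- vapply(instances, function(i) i$drug_id, "")
  out <- list()
  for (i in seq_along(instances)) {
    d <- drugs[[i]]
    degs <- call_degs(instances[[i]], log2_threshold, pseudocount)
    out[[d]] <- if (is.null(out[[d]])) degs else union(out[[d]], degs)
  }
  lapply(out[sort(names(out))], sort)
}

#' Read/write per-drug gene sets
#'
#' TSV with columns `drug_id` and `genes` (semicolon-separated; empty for a
#' drug with no affected genes).
#' @param drug_sets named list: drug id -> gene id vector.
#' @param path file path.
#' @return `write_drug_gene_sets`: `path` invisibly; `read_drug_gene_sets`:
#'   the named list.
#' @export
write_drug_gene_sets <- function(drug_sets, path) {
  df <- data.frame(drug_id = names(drug_sets),
                   genes = vapply(drug_sets, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drug_gene_sets
#' @export
read_drug_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$genes[is.na(df$genes)] <- ""
  sets <- lapply(strsplit(df$genes, ";", fixed = TRUE),
                 function(v) sort(v[nzchar(v)]))
  stats::setNames(sets, df$drug_id)
}
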