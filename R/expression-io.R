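#' Construct an expression instance
#'
#' One paired treatment/control perturbation experiment for one drug, with
#' intensity vectors aligned over a shared gene universe.
#'
#' @param instance_id,drug_id single strings.
#' @param genes character vector of gene ids (the universe order).
#' @param treatment,control non-negative numeric vectors aligned to `genes`.
#' @return an object of class `expression_instance`.
#' @export
expression_instance <- function(instance_id, drug_id, genes, treatment, control) {
  genes <- as.character(genes)
  if (length(treatment) != length(genes) || length(control) != length(genes)) {
    stop("treatment/control vectors must align with the gene universe")
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids in universe")
  if (any(treatment < 0) || any(control < 0)) stop("intensities must be non-negative")
  structure(
    list(instance_id = instance_id, drug_id = drug_id, genes = genes,
         treatment = as.numeric(treatment), control = as.numeric(control)),
    class = "expression_instance"
  )
}

#' Read paired drug perturbation expression instances
#'
#' The matrix TSV has genes in rows (first column `gene_id`) and samples in
#' columns. The annotation TSV has columns `instance_id`, `drug_id`,
#' `treatment_column`, `control_column`, pairing each treatment sample with
#' exactly one control sample and naming the perturbing drug.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param annotation_path path to the instance annotation TSV.
#' @return list of [expression_instance] objects, one per annotation row
#'   (empty list for an empty annotation table).
#' @export
read_expression_instances <- function(matrix_path, annotation_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 1L || names(mat)[[1L]] != "gene_id") {
    stop("expression matrix must have first column 'gene_id'")
  }
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("instance_id", "drug_id", "treatment_column", "control_column")
  if (nrow(ann) == 0L) return(list())
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  genes <- as.character(mat$gene_id)
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    tc <- ann$treatment_column[[i]]; cc <- ann$control_column[[i]]
    for (col in c(tc, cc)) {
      if (!col %in% names(mat)) {
        stop("annotation row ", i, " references sample column '", col,
             "' absent from the expression matrix")
      }
    }
    out[[i]] <- expression_instance(ann$instance_id[[i]], ann$drug_id[[i]],
                                    genes, mat[[tc]], mat[[cc]])
  }
  out
}

#' Write expression instances as a matrix + annotation TSV pair
#' @param instances list of [expression_instance] sharing one gene universe.
#' @param matrix_path,annotation_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_expression_instances <- function(instances, matrix_path, annotation_path) {
  if (length(instances) == 0L) {
    utils::write.table(data.frame(gene_id = character(0)), matrix_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(instance_id = character(0), drug_id = character(0),
                 treatment_column = character(0), control_column = character(0)),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(matrix = matrix_path, annotation = annotation_path)))
  }
  genes <- instances[[1L]]$genes
  cols <- list(gene_id = genes)
  ann <- data.frame(instance_id = character(0), drug_id = character(0),
                    treatment_column = character(0), control_column = character(0),
                    stringsAsFactors = FALSE)
  for (inst in instances) {
    stopifnot(identical(inst$genes, genes))
    tc <- paste0(inst$instance_id, ".trt"); cc <- paste0(inst$instance_id, ".ctl")
    cols[[tc]] <- inst$treatment; cols[[cc]] <- inst$control
    ann <- rbind(ann, data.frame(instance_id = inst$instance_id,
                                 drug_id = inst$drug_id,
                                 treatment_column = tc, control_column = cc,
                                 stringsAsFactors = FALSE))
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), matrix_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(matrix = matrix_path, annotation = annotation_path))
}
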