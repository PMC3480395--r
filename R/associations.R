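#' Construct the bundle of annotation tables
#'
#' Holds the drug- and disease-level annotations consumed downstream of the
#' network: ATC class per drug, indication/side-effect/therapeutic-target
#' sets per drug, subpathway sets and class per disease, and per-gene tissue
#' labels (housekeeping genes, tissue-specific genes with their tissues).
#' All maps may be partial: a drug without a side-effect record is simply
#' absent, mirroring the partial coverage of public side-effect resources.
#'
#' @param drug_class named character vector: drug id -> class code.
#' @param drug_indication named list: drug id -> character vector of terms.
#' @param drug_side_effects named list: drug id -> character vector of terms.
#' @param drug_targets named list: drug id -> character vector of gene ids.
#' @param disease_subpathways named list: disease id -> subpathway ids.
#' @param disease_class named character vector: disease id -> class label.
#' @param tissue_labels data.frame with columns `gene_id`,
#'   `label` (`"HKG"` or `"TEG"`) and `tissues` (semicolon-separated list,
#'   empty for HKGs; every TEG needs at least one tissue).
#' @return an object of class `association_tables`.
#' @export
association_tables <- function(drug_class = character(0),
                               drug_indication = list(),
                               drug_side_effects = list(),
                               drug_targets = list(),
                               disease_subpathways = list(),
                               disease_class = character(0),
                               tissue_labels = empty_tissue_labels()) {
  norm_map <- function(m) lapply(m, function(v) sort(unique(as.character(v))))
  tissue_labels <- as.data.frame(tissue_labels, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "label", "tissues") %in% names(tissue_labels)))
  if (!all(tissue_labels$label %in% c("HKG", "TEG"))) {
    stop("tissue labels must be 'HKG' or 'TEG'")
  }
  teg_no_tissue <- tissue_labels$label == "TEG" & !nzchar(tissue_labels$tissues)
  if (any(teg_no_tissue)) {
    stop("TEG without tissue annotation: ",
         paste(tissue_labels$gene_id[teg_no_tissue], collapse = ", "))
  }
  tissue_labels <- tissue_labels[order(tissue_labels$gene_id), , drop = FALSE]
  rownames(tissue_labels) <- NULL
  structure(
    list(drug_class = drug_class[order(names(drug_class))],
         drug_indication = norm_map(drug_indication)[sort(names(drug_indication))],
         drug_side_effects = norm_map(drug_side_effects)[sort(names(drug_side_effects))],
         drug_targets = norm_map(drug_targets)[sort(names(drug_targets))],
         disease_subpathways = norm_map(disease_subpathways)[sort(names(disease_subpathways))],
         disease_class = disease_class[order(names(disease_class))],
         tissue_labels = tissue_labels),
    class = "association_tables"
  )
}

empty_tissue_labels <- function() {
  data.frame(gene_id = character(0), label = character(0),
             tissues = character(0), stringsAsFactors = FALSE)
}

assoc_files <- c(drug_class = "drug_class.tsv",
                 drug_indication = "drug_indication.tsv",
                 drug_side_effects = "drug_side_effects.tsv",
                 drug_targets = "drug_targets.tsv",
                 disease_subpathways = "disease_subpathways.tsv",
                 disease_class = "disease_class.tsv",
                 tissue_labels = "tissue_labels.tsv")

read_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expected two columns in ", path)
  df[, 1:2]
}

pairs_to_map <- function(df) {
  if (nrow(df) == 0L) return(list())
  split(df[[2L]], df[[1L]])
}

#' Read association tables from a directory
#'
#' Any subset of the documented files may be present
#' (`drug_class.tsv`, `drug_indication.tsv`, `drug_side_effects.tsv`,
#' `drug_targets.tsv`, `disease_subpathways.tsv`, `disease_class.tsv`,
#' `tissue_labels.tsv`); missing files yield empty maps. All are two-column
#' key/value TSVs except the tissue file (columns `gene_id`, `label`,
#' `tissues`). Duplicate rows with conflicting single-valued keys (e.g. two
#' ATC classes for one drug) are an error.
#'
#' @param dir directory path.
#' @return an [association_tables] object.
#' @export
read_associations <- function(dir) {
  p <- function(f) file.path(dir, f)
  read_single <- function(file, what) {
    if (!file.exists(p(file))) return(character(0))
    df <- read_pairs(p(file))
    dup <- df[duplicated(df[[1L]]) | duplicated(df[[1L]], fromLast = TRUE), ]
    if (nrow(dup) > 0L && nrow(unique(dup)) != length(unique(dup[[1L]]))) {
      bad <- unique(dup[[1L]][ave(dup[[2L]], dup[[1L]],
                                  FUN = function(v) length(unique(v))) > 1])
      stop("conflicting ", what, " rows for: ", paste(bad, collapse = ", "))
    }
    df <- unique(df)
    stats::setNames(df[[2L]], df[[1L]])
  }
  read_multi <- function(file) {
    if (!file.exists(p(file))) return(list())
    pairs_to_map(read_pairs(p(file)))
  }
  tl <- if (file.exists(p("tissue_labels.tsv"))) {
    df <- utils::read.delim(p("tissue_labels.tsv"), stringsAsFactors = FALSE,
                            colClasses = "character")
    df$tissues[is.na(df$tissues)] <- ""
    df
  } else empty_tissue_labels()
  association_tables(
    drug_class = read_single("drug_class.tsv", "drug class"),
    drug_indication = read_multi("drug_indication.tsv"),
    drug_side_effects = read_multi("drug_side_effects.tsv"),
    drug_targets = read_multi("drug_targets.tsv"),
    disease_subpathways = read_multi("disease_subpathways.tsv"),
    disease_class = read_single("disease_class.tsv", "disease class"),
    tissue_labels = tl
  )
}

#' Write association tables to a directory
#' @param tables an [association_tables] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_associations <- function(tables, dir) {
  stopifnot(inherits(tables, "association_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  map_to_pairs <- function(m, k, v) {
    if (length(m) == 0L) {
      return(stats::setNames(data.frame(a = character(0), b = character(0)), c(k, v)))
    }
    stats::setNames(
      data.frame(rep(names(m), lengths(m)), unlist(m, use.names = FALSE),
                 stringsAsFactors = FALSE), c(k, v))
  }
  wt(stats::setNames(data.frame(names(tables$drug_class),
                                unname(tables$drug_class)),
                     c("drug_id", "atc_class")), "drug_class.tsv")
  wt(map_to_pairs(tables$drug_indication, "drug_id", "indication"),
     "drug_indication.tsv")
  wt(map_to_pairs(tables$drug_side_effects, "drug_id", "side_effect"),
     "drug_side_effects.tsv")
  wt(map_to_pairs(tables$drug_targets, "drug_id", "target_gene"),
     "drug_targets.tsv")
  wt(map_to_pairs(tables$disease_subpathways, "disease_id", "subpathway_id"),
     "disease_subpathways.tsv")
  wt(stats::setNames(data.frame(names(tables$disease_class),
                                unname(tables$disease_class)),
                     c("disease_id", "disease_class")), "disease_class.tsv")
  wt(tables$tissue_labels, "tissue_labels.tsv")
  invisible(dir)
}

#' Tissue annotation helpers
#'
#' `tissue_label_map` turns the tissue-label table into a named list of
#' per-gene tissue vectors for TEGs, plus vectors of HKG and TEG ids.
#' @param tissue_labels the `tissue_labels` data.frame of an
#'   [association_tables] object.
#' @return list with elements `hkg`, `teg` (character vectors of gene ids)
#'   and `teg_tissues` (named list of tissue vectors).
#' @export
tissue_label_map <- function(tissue_labels) {
  hkg <- tissue_labels$gene_id[tissue_labels$label == "HKG"]
  teg_rows <- tissue_labels[tissue_labels$label == "TEG", , drop = FALSE]
  teg_tissues <- lapply(strsplit(teg_rows$tissues, ";", fixed = TRUE),
                        function(v) sort(unique(v[nzchar(v)])))
  names(teg_tissues) <- teg_rows$gene_id
  list(hkg = hkg, teg = teg_rows$gene_id, teg_tissues = teg_tissues)
}
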