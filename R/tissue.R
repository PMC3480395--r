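#' Classify network subpathways as therapeutic or non-therapeutic
#'
#' A subpathway is therapeutic when some drug linked to it has a
#' therapeutic target among that drug's own affected genes falling inside
#' the subpathway; all other network subpathways are non-therapeutic. The
#' classification is drug-specific by default: only a linked drug's own
#' targets can make a subpathway therapeutic. With `global_targets = TRUE`
#' any recorded target of any drug inside the affected genes counts
#' (the looser reading).
#'
#' @param net a [drsn].
#' @param drug_sets named list: drug id -> affected gene ids.
#' @param drug_targets named list: drug id -> therapeutic target gene ids
#'   (partial coverage is expected).
#' @param catalog subpathway catalog covering all network subpathways.
#' @param global_targets use the pooled-target variant.
#' @return named character vector: subpathway id -> `"therapeutic"` or
#'   `"non_therapeutic"`, total over the network's subpathways.
#' @export
classify_subpathways <- function(net, drug_sets, drug_targets, catalog,
                                 global_targets = FALSE) {
  missing_sp <- setdiff(net$subpathway_nodes, names(catalog))
  if (length(missing_sp) > 0L) {
    stop("network subpathway(s) absent from catalog: ",
         paste(missing_sp, collapse = ", "))
  }
  all_targets <- unique(unlist(drug_targets, use.names = FALSE))
  nb <- subpathway_neighbours(net)
  out <- stats::setNames(rep("non_therapeutic", length(net$subpathway_nodes)),
                         net$subpathway_nodes)
  for (sp in net$subpathway_nodes) {
    sp_genes <- catalog[[sp]]$genes
    for (d in nb[[sp]]) {
      affected_in_sp <- intersect(drug_sets[[d]], sp_genes)
      targets <- if (global_targets) all_targets else drug_targets[[d]]
      if (length(intersect(affected_in_sp, targets)) > 0L) {
        out[[sp]] <- "therapeutic"
        break
      }
    }
  }
  out
}

#' Degree comparison of therapeutic vs non-therapeutic subpathways
#'
#' One-sided Wilcoxon rank-sum tests of subpathway degree: therapeutic vs
#' non-therapeutic, and therapeutic vs all network subpathways.
#'
#' @param net a [drsn].
#' @param classes named vector from [classify_subpathways].
#' @return list with the two p-values, the rank-sum statistic of the main
#'   comparison, and per-group median degrees.
#' @export
degree_comparison <- function(net, classes) {
  deg <- network_stats(net)$subpathway_degrees
  th <- deg[names(classes)[classes == "therapeutic"]]
  nth <- deg[names(classes)[classes == "non_therapeutic"]]
  if (length(th) == 0L || length(nth) == 0L) {
    stop("both subpathway classes must be non-empty")
  }
  wt <- stats::wilcox.test(th, nth, alternative = "greater", exact = FALSE)
  wt_all <- stats::wilcox.test(th, deg, alternative = "greater", exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_value_vs_all = wt_all$p.value,
       medians = c(therapeutic = stats::median(th),
                   non_therapeutic = stats::median(nth),
                   all = stats::median(deg)))
}

#' Tissue-homogeneity coefficient of a TEG set
#'
#' TH = max over tissues j of (number of the given TEGs expressed in j) /
#' (number of TEGs). TH is 1 when all TEGs co-express in one tissue and 0
#' when the set is empty; a multi-tissue TEG counts once for each of its
#' tissues. Ties between tissues break lexicographically.
#'
#' @param affected_tegs character vector of TEG gene ids.
#' @param teg_tissues named list: TEG gene id -> tissue vector (as from
#'   [tissue_label_map]).
#' @return list with `th` (in \[0, 1\]) and `top_tissue` (`NA` when
#'   `th` is 0).
#' @export
th_coefficient <- function(affected_tegs, teg_tissues) {
  affected_tegs <- unique(affected_tegs)
  if (length(affected_tegs) == 0L) {
    return(list(th = 0, top_tissue = NA_character_))
  }
  unannotated <- setdiff(affected_tegs, names(teg_tissues))
  if (length(unannotated) > 0L) {
    stop("TEG without tissue annotation: ", paste(unannotated, collapse = ", "))
  }
  counts <- table(unlist(teg_tissues[affected_tegs], use.names = FALSE))
  if (length(counts) == 0L) stop("TEGs carry empty tissue sets")
  tissues <- sort(names(counts))
  counts <- counts[tissues]
  top <- tissues[[which.max(counts)]]  # which.max takes the first = lexicographic tie-break
  list(th = as.numeric(max(counts)) / length(affected_tegs), top_tissue = top)
}

#' Tissue profiles of network subpathways
#'
#' For every network subpathway: the union over linked drugs of
#' drug-affected genes inside the subpathway, the fractions of those genes
#' that are TEGs and HKGs, and the tissue-homogeneity coefficient with its
#' top tissue. Subpathways with no affected genes get `NA` ratios.
#'
#' @param net a [drsn].
#' @param drug_sets named list: drug id -> affected gene ids.
#' @param catalog subpathway catalog.
#' @param classes named vector from [classify_subpathways].
#' @param tissue_labels tissue-label data.frame (see [association_tables]).
#' @return data.frame with columns `subpathway_id`, `class`, `n_affected`,
#'   `teg_ratio`, `hkg_ratio`, `th`, `top_tissue`.
#' @export
subpathway_tissue_profiles <- function(net, drug_sets, catalog, classes,
                                       tissue_labels) {
  tl <- tissue_label_map(tissue_labels)
  nb <- subpathway_neighbours(net)
  rows <- lapply(net$subpathway_nodes, function(sp) {
    affected <- sort(unique(unlist(lapply(nb[[sp]], function(d)
      intersect(drug_sets[[d]], catalog[[sp]]$genes)), use.names = FALSE)))
    n <- length(affected)
    tegs <- intersect(affected, tl$teg)
    thc <- th_coefficient(tegs, tl$teg_tissues)
    data.frame(subpathway_id = sp, class = unname(classes[[sp]]),
               n_affected = n,
               teg_ratio = if (n > 0L) length(tegs) / n else NA_real_,
               hkg_ratio = if (n > 0L) length(intersect(affected, tl$hkg)) / n
                           else NA_real_,
               th = thc$th, top_tissue = thc$top_tissue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare TEG/HKG composition between subpathway classes
#'
#' Ratios are per subpathway: |affected genes with the label| / |affected
#' genes|. TEG ratios are compared one-sided (therapeutic greater) and HKG
#' ratios two-sided, by Wilcoxon rank-sum tests; therapeutic-vs-all
#' companions are included. Subpathways with zero affected genes are
#' excluded.
#'
#' @param profiles data.frame from [subpathway_tissue_profiles].
#' @return list with class means and the four p-values.
#' @export
composition_ratios <- function(profiles) {
  profiles <- profiles[!is.na(profiles$teg_ratio), , drop = FALSE]
  th <- profiles[profiles$class == "therapeutic", , drop = FALSE]
  nth <- profiles[profiles$class == "non_therapeutic", , drop = FALSE]
  if (nrow(th) == 0L || nrow(nth) == 0L) stop("both classes must be non-empty")
  w <- function(x, y, alt) stats::wilcox.test(x, y, alternative = alt,
                                              exact = FALSE)$p.value
  list(mean_teg_ratio = c(therapeutic = mean(th$teg_ratio),
                          non_therapeutic = mean(nth$teg_ratio),
                          all = mean(profiles$teg_ratio)),
       mean_hkg_ratio = c(therapeutic = mean(th$hkg_ratio),
                          non_therapeutic = mean(nth$hkg_ratio),
                          all = mean(profiles$hkg_ratio)),
       teg_p = w(th$teg_ratio, nth$teg_ratio, "greater"),
       teg_p_vs_all = w(th$teg_ratio, profiles$teg_ratio, "greater"),
       hkg_p = w(th$hkg_ratio, nth$hkg_ratio, "two.sided"),
       hkg_p_vs_all = w(th$hkg_ratio, profiles$hkg_ratio, "two.sided"))
}

#' Per-tissue sums of tissue-homogeneity coefficients
#'
#' Each subpathway contributes its TH value to the bucket of its most
#' affected tissue (the TH argmax) within its class; profiles with TH 0
#' contribute nowhere.
#'
#' @param profiles data.frame from [subpathway_tissue_profiles].
#' @return named list of named numeric vectors: class -> tissue -> TH sum.
#' @export
tissue_th_sums <- function(profiles) {
  out <- list()
  for (cl in sort(unique(profiles$class))) {
    sub <- profiles[profiles$class == cl & profiles$th > 0 &
                      !is.na(profiles$top_tissue), , drop = FALSE]
    sums <- tapply(sub$th, sub$top_tissue, sum)
    out[[cl]] <- stats::setNames(as.numeric(sums), names(sums))
  }
  out
}

#' Compare TH coefficients between subpathway classes
#'
#' One-sided Wilcoxon rank-sum test of TH coefficients, therapeutic
#' greater than non-therapeutic.
#'
#' @param profiles data.frame from [subpathway_tissue_profiles].
#' @return list with `statistic`, `p_value`, and class mean TH values.
#' @export
th_class_comparison <- function(profiles) {
  th <- profiles$th[profiles$class == "therapeutic"]
  nth <- profiles$th[profiles$class == "non_therapeutic"]
  if (length(th) == 0L || length(nth) == 0L) {
    stop("both classes need at least one profile")
  }
  wt <- stats::wilcox.test(th, nth, alternative = "greater", exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       means = c(therapeutic = mean(th), non_therapeutic = mean(nth)))
}
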