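#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. Defaults describe a small but realistic world: ten metabolic
#' pathways of 8-14 enzyme nodes, thirty drugs each perturbing the genes of
#' two subpathways with a planted four-fold (log2 effect 2) change under
#' moderate multiplicative noise, class-structured indications and
#' disease-subpathway blocks, and a tissue annotation with housekeeping
#' and tissue-specific genes.
#'
#' @param seed integer seed; the whole generation chain is deterministic
#'   given it.
#' @param n_pathways number of pathway graphs.
#' @param pathway_size_range integer range of nodes per pathway.
#' @param edge_density probability of each extra (non-spanning-tree) edge;
#'   0 yields trees.
#' @param genes_per_node_range integer range of genes annotated per node.
#' @param n_decoy_genes genes in the expression universe that belong to no
#'   pathway (they can be called as DEGs but never enrich).
#' @param n_drugs number of drugs.
#' @param instances_per_drug_range integer range of paired instances per drug.
#' @param n_target_subpathways_per_drug planted subpathways per drug.
#' @param planted_log2_effect log2 fold change applied to planted genes.
#' @param noise_sd standard deviation of the per-arm multiplicative
#'   log-normal noise, on the log2 scale.
#' @param background_deg_rate probability that an off-target gene is also
#'   perturbed in an instance.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale location/spread of
#'   baseline intensities (array-like, mean about 7).
#' @param n_diseases,n_drug_classes,n_disease_classes class structure sizes.
#' @param class_subpathway_overlap probability that a disease inherits each
#'   subpathway of its matched drug class block (planted class association).
#' @param indication_vocabulary_size,side_effect_vocabulary_size term
#'   vocabulary sizes.
#' @param side_effect_sharing_prob probability that a drug planted on a
#'   term's anchor subpathway carries the term; co-linked drugs therefore
#'   share terms.
#' @param baseline_prob probability that any other drug carries the term.
#' @param indication_class_prob probability a drug carries each indication
#'   of its class block.
#' @param indication_baseline_prob background indication rate.
#' @param fraction_hkg,fraction_teg fractions of the gene universe labelled
#'   HKG / TEG.
#' @param n_tissues number of tissues TEGs can be specific to.
#' @param therapeutic_target_rate per-gene probability that a planted gene
#'   of a drug is recorded as its therapeutic target; the default 0.02
#'   yields roughly one target per drug, the scale seen in curated
#'   drug-target resources.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_pathways = 10L,
                              pathway_size_range = c(8L, 14L),
                              edge_density = 0.15,
                              genes_per_node_range = c(1L, 3L),
                              n_decoy_genes = 100L,
                              n_drugs = 30L,
                              instances_per_drug_range = c(1L, 3L),
                              n_target_subpathways_per_drug = 2L,
                              planted_log2_effect = 2,
                              noise_sd = 0.3,
                              background_deg_rate = 0.01,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1,
                              n_diseases = 20L,
                              n_drug_classes = 4L,
                              n_disease_classes = 4L,
                              class_subpathway_overlap = 0.8,
                              indication_vocabulary_size = 20L,
                              side_effect_vocabulary_size = 50L,
                              side_effect_sharing_prob = 0.3,
                              baseline_prob = 0.02,
                              indication_class_prob = 0.7,
                              indication_baseline_prob = 0.05,
                              fraction_hkg = 0.15,
                              fraction_teg = 0.25,
                              n_tissues = 10L,
                              therapeutic_target_rate = 0.02) {
  cfg <- as.list(environment())
  probs <- c(cfg$edge_density, cfg$background_deg_rate,
             cfg$class_subpathway_overlap, cfg$side_effect_sharing_prob,
             cfg$baseline_prob, cfg$indication_class_prob,
             cfg$indication_baseline_prob, cfg$fraction_hkg, cfg$fraction_teg,
             cfg$therapeutic_target_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$fraction_hkg + cfg$fraction_teg <= 1,
            cfg$noise_sd >= 0, cfg$planted_log2_effect >= 0,
            diff(cfg$pathway_size_range) >= 0,
            diff(cfg$genes_per_node_range) >= 0,
            diff(cfg$instances_per_drug_range) >= 0)
  structure(cfg, class = "simulation_config")
}

sample_range <- function(rng) {
  if (rng[[1L]] == rng[[2L]]) rng[[1L]] else sample(rng[[1L]]:rng[[2L]], 1L)
}

#' Generate random pathway graphs
#'
#' Each pathway is a random spanning tree over its nodes (guaranteeing
#' connectivity) plus extra edges added independently with probability
#' `edge_density`; every node is annotated with genes drawn without
#' replacement from a fresh universe, so pathways do not share genes.
#'
#' @param cfg a [simulation_config].
#' @return list of [pathway_graph] objects.
#' @export
generate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  gene_counter <- 0L
  lapply(seq_len(cfg$n_pathways), function(i) {
    n <- sample_range(cfg$pathway_size_range)
    nodes <- sprintf("E%02d", seq_len(n))
    edges <- if (n > 1L) {
      cbind(nodes[vapply(2:n, function(j) sample.int(j - 1L, 1L), 0L)],
            nodes[2:n])
    } else matrix(character(0), ncol = 2L)
    if (n > 2L && cfg$edge_density > 0) {
      allp <- utils::combn(n, 2L)
      extra <- stats::runif(ncol(allp)) < cfg$edge_density
      edges <- rbind(edges, cbind(nodes[allp[1L, extra]], nodes[allp[2L, extra]]))
    }
    node_genes <- lapply(seq_len(n), function(j) {
      ng <- sample_range(cfg$genes_per_node_range)
      ids <- sprintf("G%05d", gene_counter + seq_len(ng))
      gene_counter <<- gene_counter + ng
      ids
    })
    names(node_genes) <- nodes
    pathway_graph(sprintf("path:sim%02d", i), sprintf("simulated pathway %d", i),
                  nodes, edges, node_genes)
  })
}

#' Generate drug perturbation expression instances with planted signal
#'
#' Per drug, `n_target_subpathways_per_drug` subpathways are chosen from
#' the catalog; the union of their genes is that drug's planted gene set.
#' Per instance, baseline intensities are log-normal (log2 mean about 7),
#' planted genes are multiplied by `2^planted_log2_effect` in the treatment
#' arm, a `background_deg_rate` fraction of off-target genes is also
#' perturbed, and both arms receive independent multiplicative log-normal
#' noise of log2-scale sd `noise_sd`. The planted drug -> subpathway map is
#' returned as first-class ground truth.
#'
#' @param cfg a [simulation_config].
#' @param pathways list of [pathway_graph] from [generate_pathways].
#' @param catalog subpathway catalog mined from those pathways.
#' @return list with `instances` (list of [expression_instance]),
#'   `ground_truth` (named list: drug id -> planted subpathway ids),
#'   `universe` (gene id vector).
#' @export
generate_expression <- function(cfg, pathways, catalog) {
  stopifnot(inherits(cfg, "simulation_config"), length(catalog) > 0L)
  set.seed(cfg$seed + 1L)
  pw_genes <- sort(unique(unlist(lapply(pathways, pathway_genes),
                                 use.names = FALSE)))
  decoys <- if (cfg$n_decoy_genes > 0L) sprintf("X%05d", seq_len(cfg$n_decoy_genes))
            else character(0)
  universe <- c(pw_genes, decoys)
  G <- length(universe)
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  sp_ids <- names(catalog)
  ground_truth <- stats::setNames(vector("list", length(drugs)), drugs)
  instances <- list()
  for (d in drugs) {
    targets <- sort(sample(sp_ids, min(cfg$n_target_subpathways_per_drug,
                                       length(sp_ids))))
    ground_truth[[d]] <- targets
    planted <- intersect(universe,
                         unique(unlist(catalog_gene_sets(catalog)[targets],
                                       use.names = FALSE)))
    n_inst <- sample_range(cfg$instances_per_drug_range)
    for (r in seq_len(n_inst)) {
      control <- 2^stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
      effect <- numeric(G)
      effect[match(planted, universe)] <- cfg$planted_log2_effect
      if (cfg$background_deg_rate > 0) {
        off <- which(effect == 0)
        bg <- off[stats::runif(length(off)) < cfg$background_deg_rate]
        effect[bg] <- sample(c(-1, 1), length(bg), replace = TRUE) *
          cfg$planted_log2_effect
      }
      treatment <- control * 2^effect
      if (cfg$noise_sd > 0) {
        treatment <- treatment * 2^stats::rnorm(G, 0, cfg$noise_sd)
        control <- control * 2^stats::rnorm(G, 0, cfg$noise_sd)
      }
      iid <- sprintf("%s.i%02d", d, r)
      instances[[iid]] <- expression_instance(iid, d, universe, treatment, control)
    }
  }
  list(instances = unname(instances), ground_truth = ground_truth,
       universe = universe)
}

#' Generate association tables consistent with planted structure
#'
#' Drugs are split round-robin into drug classes and diseases into disease
#' classes. Indications come in class blocks; side-effect terms are
#' anchored to subpathways so that drugs planted on the same subpathway
#' share terms at `side_effect_sharing_prob` versus `baseline_prob`
#' otherwise; each disease samples the subpathway block of its matched
#' drug class (class i with class i, recycled) at
#' `class_subpathway_overlap`; tissue labels split the universe into HKGs,
#' single-tissue TEGs and unlabelled genes; therapeutic targets are drawn
#' from each drug's planted genes at `therapeutic_target_rate`.
#'
#' @param cfg a [simulation_config].
#' @param ground_truth named list: drug id -> planted subpathway ids.
#' @param catalog subpathway catalog.
#' @param universe gene universe of the expression stage.
#' @return an [association_tables] object.
#' @export
generate_annotations <- function(cfg, ground_truth, catalog, universe) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  drugs <- names(ground_truth)
  sp_ids <- names(catalog)
  gene_sets <- catalog_gene_sets(catalog)

  drug_class <- stats::setNames(
    sprintf("C%02d", rep_len(seq_len(cfg$n_drug_classes), length(drugs))), drugs)

  ind_vocab <- sprintf("ind%03d", seq_len(cfg$indication_vocabulary_size))
  blocks <- split(ind_vocab, rep_len(seq_len(cfg$n_drug_classes),
                                     length(ind_vocab)))
  drug_indication <- lapply(drugs, function(d) {
    cls <- match(drug_class[[d]], sprintf("C%02d", seq_len(cfg$n_drug_classes)))
    block <- blocks[[cls]]
    own <- block[stats::runif(length(block)) < cfg$indication_class_prob]
    extra <- ind_vocab[stats::runif(length(ind_vocab)) < cfg$indication_baseline_prob]
    sort(unique(c(own, extra)))
  })
  names(drug_indication) <- drugs
  drug_indication <- drug_indication[lengths(drug_indication) > 0L]

  se_vocab <- sprintf("se%03d", seq_len(cfg$side_effect_vocabulary_size))
  anchors <- sample(sp_ids, length(se_vocab), replace = TRUE)
  drug_side_effects <- stats::setNames(
    lapply(drugs, function(d) character(0)), drugs)
  for (t in seq_along(se_vocab)) {
    on_anchor <- vapply(drugs, function(d) anchors[[t]] %in% ground_truth[[d]],
                        TRUE)
    p <- ifelse(on_anchor, cfg$side_effect_sharing_prob, cfg$baseline_prob)
    carriers <- drugs[stats::runif(length(drugs)) < p]
    for (d in carriers) {
      drug_side_effects[[d]] <- c(drug_side_effects[[d]], se_vocab[[t]])
    }
  }
  drug_side_effects <- lapply(drug_side_effects, sort)
  drug_side_effects <- drug_side_effects[lengths(drug_side_effects) > 0L]

  drug_targets <- lapply(drugs, function(d) {
    planted <- unique(unlist(gene_sets[ground_truth[[d]]], use.names = FALSE))
    sort(planted[stats::runif(length(planted)) < cfg$therapeutic_target_rate])
  })
  names(drug_targets) <- drugs
  drug_targets <- drug_targets[lengths(drug_targets) > 0L]

  diseases <- sprintf("disease%03d", seq_len(cfg$n_diseases))
  disease_class <- stats::setNames(
    sprintf("D%02d", rep_len(seq_len(cfg$n_disease_classes), length(diseases))),
    diseases)
  class_blocks <- lapply(seq_len(cfg$n_disease_classes), function(j) {
    dc <- sprintf("C%02d", 1L + (j - 1L) %% cfg$n_drug_classes)
    sort(unique(unlist(ground_truth[names(drug_class)[drug_class == dc]],
                       use.names = FALSE)))
  })
  disease_subpathways <- lapply(diseases, function(ds) {
    j <- match(disease_class[[ds]], sprintf("D%02d", seq_len(cfg$n_disease_classes)))
    block <- class_blocks[[j]]
    own <- block[stats::runif(length(block)) < cfg$class_subpathway_overlap]
    sort(unique(own))
  })
  names(disease_subpathways) <- diseases
  disease_subpathways <- disease_subpathways[lengths(disease_subpathways) > 0L]
  disease_class <- disease_class[names(disease_class) %in% names(disease_subpathways)]

  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  lab <- sample(c("HKG", "TEG", "other"), length(universe), replace = TRUE,
                prob = c(cfg$fraction_hkg, cfg$fraction_teg,
                         1 - cfg$fraction_hkg - cfg$fraction_teg))
  keep <- lab != "other"
  tissue_labels <- data.frame(
    gene_id = universe[keep], label = lab[keep],
    tissues = ifelse(lab[keep] == "TEG",
                     sample(tissues, sum(keep), replace = TRUE), ""),
    stringsAsFactors = FALSE)

  association_tables(drug_class = drug_class,
                     drug_indication = drug_indication,
                     drug_side_effects = drug_side_effects,
                     drug_targets = drug_targets,
                     disease_subpathways = disease_subpathways,
                     disease_class = disease_class,
                     tissue_labels = tissue_labels)
}

#' Generate and write a complete input directory
#'
#' Runs the whole generation chain (pathways -> mining -> expression ->
#' annotations) and writes every artifact the pipeline consumes, plus the
#' ground-truth drug -> planted-subpathway table, under `dir`.
#'
#' @param cfg a [simulation_config].
#' @param dir output directory (created).
#' @param k,min_size mining parameters used for the planted catalog.
#' @return invisibly, a list with the in-memory objects
#'   (`pathways`, `catalog`, `instances`, `ground_truth`, `universe`,
#'   `tables`) and `dir`.
#' @export
simulate_drsn_inputs <- function(cfg, dir, k = 3, min_size = 2) {
  dir.create(file.path(dir, "pathways"), showWarnings = FALSE, recursive = TRUE)
  pathways <- generate_pathways(cfg)
  for (p in pathways) {
    write_pathway(p, file.path(dir, "pathways",
                               paste0(gsub(":", "_", p$pathway_id), ".tsv")))
  }
  catalog <- mine_all(pathways, k = k, min_size = min_size)
  write_catalog(catalog, file.path(dir, "catalog.tsv"))
  expr <- generate_expression(cfg, pathways, catalog)
  write_expression_instances(expr$instances, file.path(dir, "expression.tsv"),
                             file.path(dir, "instances.tsv"))
  tables <- generate_annotations(cfg, expr$ground_truth, catalog, expr$universe)
  write_associations(tables, file.path(dir, "associations"))
  gt <- data.frame(drug_id = rep(names(expr$ground_truth),
                                 lengths(expr$ground_truth)),
                   subpathway_id = unlist(expr$ground_truth, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(pathways = pathways, catalog = catalog,
                 instances = expr$instances, ground_truth = expr$ground_truth,
                 universe = expr$universe, tables = tables, dir = dir))
}
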