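#' Pipeline run configuration
#'
#' Bundles every threshold of the end-to-end analysis. Defaults mirror the
#' reference setting: distance bound k = 3, enrichment threshold
#' alpha = 0.01, DEG threshold |log2 fold change| > 1, 1000 random networks
#' and 1000 permutations (scale `n_random`/`n_perm` down for quick runs).
#'
#' @param input_dir directory of inputs (as written by
#'   [simulate_drsn_inputs]); ignored when `simulate = TRUE` and created.
#' @param out_dir directory for stage outputs (created).
#' @param k,min_size subpathway mining parameters.
#' @param log2_threshold,pseudocount DEG-calling parameters.
#' @param alpha enrichment significance threshold.
#' @param n_random random networks for the null comparison.
#' @param n_perm permutations for the indication test.
#' @param seed integer seed for every stochastic stage.
#' @param background `"pathways"` (union of pathway-annotated genes, the
#'   default convention) or `"universe"` (all measured genes).
#' @param simulate generate inputs first with [simulation_config] defaults
#'   (seeded from `seed`).
#' @param sim_config optional [simulation_config] overriding the default
#'   when `simulate = TRUE`.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, k = 3, min_size = 2,
                       log2_threshold = 1, pseudocount = 1, alpha = 0.01,
                       n_random = 1000L, n_perm = 1000L, seed = 1L,
                       background = c("pathways", "universe"),
                       simulate = FALSE, sim_config = NULL) {
  background <- match.arg(background)
  structure(list(input_dir = input_dir, out_dir = out_dir, k = k,
                 min_size = min_size, log2_threshold = log2_threshold,
                 pseudocount = pseudocount, alpha = alpha,
                 n_random = as.integer(n_random), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), background = background,
                 simulate = simulate, sim_config = sim_config),
            class = "run_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> mine -> degs -> network -> pairs ->
#' disease -> tissue in dependency order, writing each stage's output as an
#' independently readable TSV under `config$out_dir` together with a
#' provenance record of the configuration. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config a [run_config].
#' @return invisibly, a list of the in-memory stage results (`catalog`,
#'   `drug_sets`, `network`, `stats`, `pairs`, `indication_test`,
#'   `side_effect_test`, `trend`, `association`, `classes`, `profiles`,
#'   `summary`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- vapply(config[!vapply(config, is.null, TRUE) &
                          !names(config) %in% "sim_config"],
                 function(v) paste(format(v), collapse = " "), "")
  utils::write.table(data.frame(key = names(prov), value = unname(prov)),
                     file.path(config$out_dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(config$simulate)) {
    cfg <- if (is.null(config$sim_config)) simulation_config(seed = config$seed)
           else config$sim_config
    stage_try("simulate", simulate_drsn_inputs(cfg, config$input_dir,
                                               k = config$k,
                                               min_size = config$min_size))
  }

  pathways <- stage_try("mine", {
    files <- sort(list.files(file.path(config$input_dir, "pathways"),
                             full.names = TRUE))
    if (length(files) == 0L) stop("no pathway files in ",
                                  file.path(config$input_dir, "pathways"))
    lapply(files, read_pathway)
  })
  catalog <- stage_try("mine", mine_all(pathways, config$k, config$min_size))
  write_catalog(catalog, file.path(config$out_dir, "catalog.tsv"))

  instances <- stage_try("degs", read_expression_instances(
    file.path(config$input_dir, "expression.tsv"),
    file.path(config$input_dir, "instances.tsv")))
  drug_sets <- stage_try("degs", merge_drug_genes(instances,
                                                  config$log2_threshold,
                                                  config$pseudocount))
  write_drug_gene_sets(drug_sets, file.path(config$out_dir, "drug_genes.tsv"))

  background <- if (config$background == "pathways") {
    sort(unique(unlist(lapply(pathways, pathway_genes), use.names = FALSE)))
  } else instances[[1L]]$genes

  built <- stage_try("network",
                     suppressWarnings(build_drsn(drug_sets, catalog, background,
                                                 config$alpha)))
  net <- built$network
  write_drsn_edges(net, file.path(config$out_dir, "drsn_edges.tsv"))
  st <- network_stats(net)

  tables <- stage_try("pairs", read_associations(
    file.path(config$input_dir, "associations")))
  pairs <- stage_try("pairs", connected_drug_pairs(
    net, drug_indication = tables$drug_indication,
    drug_side_effects = tables$drug_side_effects))
  utils::write.table(pairs, file.path(config$out_dir, "drug_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ind_universe <- intersect(net$drug_nodes, names(tables$drug_indication))
  indication_test <- if (length(ind_universe) >= 2L && nrow(pairs) > 0L) {
    stage_try("pairs", shared_indication_test(pairs, tables$drug_indication,
                                              ind_universe, config$n_perm,
                                              config$seed))
  } else NULL
  se_drugs <- intersect(net$drug_nodes, names(tables$drug_side_effects))
  side_effect_test <- if (length(se_drugs) >= 2L && nrow(pairs) > 0L) {
    stage_try("pairs", shared_side_effect_comparison(pairs,
                                                     tables$drug_side_effects,
                                                     se_drugs))
  } else NULL
  trend <- tryCatch(shared_subpathway_trend(pairs), error = function(e) NULL)

  association <- if (length(tables$disease_subpathways) > 0L &&
                     length(tables$drug_class) > 0L) {
    pop <- length(unique(c(names(catalog),
                           unlist(tables$disease_subpathways,
                                  use.names = FALSE))))
    a <- stage_try("disease", association_scores(net, tables,
                                                 population = pop))
    utils::write.table(cbind(drug_class = rownames(a$scores),
                             as.data.frame(a$scores)),
                       file.path(config$out_dir, "association_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(a$pair_results,
                       file.path(config$out_dir, "drug_disease_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    a
  } else NULL

  classes <- stage_try("tissue", classify_subpathways(net, drug_sets,
                                                      tables$drug_targets,
                                                      catalog))
  profiles <- stage_try("tissue", subpathway_tissue_profiles(
    net, drug_sets, catalog, classes, tables$tissue_labels))
  utils::write.table(profiles, file.path(config$out_dir, "tissue_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- c(n_pathways = length(pathways),
               n_subpathways_mined = length(catalog),
               n_drugs_tested = length(drug_sets),
               n_drugs = st$n_drugs, n_subpathways = st$n_subpathways,
               n_nodes = st$n_nodes, n_edges = st$n_edges,
               giant_component = st$giant_component_size,
               max_drug_degree = st$max_drug_degree,
               max_subpathway_degree = st$max_subpathway_degree,
               n_connected_pairs = nrow(pairs),
               indication_p = if (is.null(indication_test)) NA else
                 indication_test$empirical_p,
               side_effect_p = if (is.null(side_effect_test)) NA else
                 side_effect_test$p_value,
               trend_slope = if (is.null(trend)) NA else trend$slope,
               n_therapeutic = sum(classes == "therapeutic"),
               n_non_therapeutic = sum(classes == "non_therapeutic"))
  utils::write.table(data.frame(statistic = names(summary),
                                value = unname(summary)),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(catalog = catalog, drug_sets = drug_sets, network = net,
                 stats = st, pairs = pairs, indication_test = indication_test,
                 side_effect_test = side_effect_test, trend = trend,
                 association = association, classes = classes,
                 profiles = profiles, summary = summary))
}

#' Validate an external drug-subpathway edge table
#'
#' Reads a published drug-subpathway association table in the three-column
#' edge dialect and prints/returns its descriptive network statistics
#' (node counts, edges, giant component, degree extremes, top subpathway
#' degrees and the maximum shared-subpathway count among drug pairs).
#'
#' @param path edge TSV path.
#' @param quiet suppress printing.
#' @return list of statistics, invisibly when printing.
#' @export
validate_drsn_file <- function(path, quiet = FALSE) {
  net <- read_drsn_edges(path)
  st <- network_stats(net)
  pairs <- connected_drug_pairs(net)
  out <- list(
    n_nodes = st$n_nodes, n_drugs = st$n_drugs,
    n_subpathways = st$n_subpathways, n_edges = st$n_edges,
    giant_component_size = st$giant_component_size,
    max_drug_degree = st$max_drug_degree,
    max_drug = names(st$drug_degrees)[which.max(st$drug_degrees)],
    max_subpathway_degree = st$max_subpathway_degree,
    subpathways_degree_gt_50 = names(st$subpathway_degrees)[
      st$subpathway_degrees > 50],
    max_shared_subpathways = if (nrow(pairs)) max(pairs$shared_subpathways)
                             else 0L)
  if (!quiet) {
    for (k in names(out)) {
      cat(sprintf("%-28s %s\n", k, paste(out[[k]], collapse = ", ")))
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher: `drsn_cli(c("all", "--out", "run1",
#' "--simulate", "--seed", "7"))` runs the full pipeline;
#' `drsn_cli(c("validate-s2", "--edges", "file.tsv"))` prints network
#' statistics of an external edge table. Flags map to [run_config] fields
#' (`--in`, `--out`, `--k`, `--min-size`, `--log2-threshold`, `--alpha`,
#' `--n-random`, `--n-perm`, `--seed`, `--background`, `--simulate`).
#'
#' @param args character vector of command-line arguments.
#' @return the subcommand's result, invisibly.
#' @export
drsn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) stop("usage: drsn <all|validate-s2> [flags]")
  cmd <- args[[1L]]; args <- args[-1L]
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (key == "simulate") { flags$simulate <- TRUE; i <- i + 1L }
    else { flags[[key]] <- args[[i + 1L]]; i <- i + 2L }
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  if (cmd == "validate-s2") {
    if (is.null(flags$edges)) stop("validate-s2 needs --edges <file>")
    return(invisible(validate_drsn_file(flags$edges)))
  }
  if (cmd != "all") stop("unknown subcommand: ", cmd)
  out <- if (is.null(flags$out)) "drsn_run" else flags$out
  cfg <- run_config(
    input_dir = if (is.null(flags[["in"]])) file.path(out, "inputs")
                else flags[["in"]],
    out_dir = out,
    k = num(flags$k, 3), min_size = num(flags[["min-size"]], 2),
    log2_threshold = num(flags[["log2-threshold"]], 1),
    alpha = num(flags$alpha, 0.01),
    n_random = num(flags[["n-random"]], 1000),
    n_perm = num(flags[["n-perm"]], 1000),
    seed = num(flags$seed, 1),
    background = if (is.null(flags$background)) "pathways" else flags$background,
    simulate = isTRUE(flags$simulate))
  invisible(run_all(cfg))
}
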