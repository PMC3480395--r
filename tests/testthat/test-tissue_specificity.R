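tissue_setup <- function() {
  catalog <- toy_catalog(list(sp1 = c("G1", "G2", "G3"),
                              sp2 = c("G4", "G5"),
                              sp3 = c("G6", "G7")))
  net <- toy_drsn(c("dA", "sp1"), c("dA", "sp2"), c("dB", "sp2"),
                  c("dB", "sp3"))
  drug_sets <- list(dA = c("G1", "G2", "G4"), dB = c("G4", "G6", "G7"))
  list(catalog = catalog, net = net, drug_sets = drug_sets)
}

test_that("classification is drug-specific and total", {
  s <- tissue_setup()
  targets <- list(dA = "G1")  # dA affects G1 inside sp1
  cls <- classify_subpathways(s$net, s$drug_sets, targets, s$catalog)
  expect_identical(unname(cls[c("sp1", "sp2", "sp3")]),
                   c("therapeutic", "non_therapeutic", "non_therapeutic"))
  expect_setequal(names(cls), s$net$subpathway_nodes)

  # the target must fall inside the subpathway's genes
  cls2 <- classify_subpathways(s$net, s$drug_sets, list(dA = "G9"), s$catalog)
  expect_true(all(cls2 == "non_therapeutic"))
  # and must belong to the linked drug itself under the default reading
  cls3 <- classify_subpathways(s$net, s$drug_sets, list(dB = "G1"), s$catalog)
  expect_identical(unname(cls3["sp1"]), "non_therapeutic")
  expect_identical(
    unname(classify_subpathways(s$net, s$drug_sets, list(dB = "G1"),
                                s$catalog, global_targets = TRUE)["sp1"]),
    "therapeutic")
  # no targets anywhere -> nothing therapeutic
  expect_true(all(classify_subpathways(s$net, s$drug_sets, list(),
                                       s$catalog) == "non_therapeutic"))
  expect_error(classify_subpathways(s$net, s$drug_sets, list(),
                                    s$catalog["sp1"]), "absent from catalog")
})

test_that("adding a target never flips therapeutic to non-therapeutic", {
  set.seed(13)
  s <- tissue_setup()
  base_targets <- list(dA = "G1")
  base <- classify_subpathways(s$net, s$drug_sets, base_targets, s$catalog)
  for (extra in c("G2", "G4", "G6", "G9")) {
    for (d in c("dA", "dB")) {
      t2 <- base_targets
      t2[[d]] <- unique(c(t2[[d]], extra))
      cls <- classify_subpathways(s$net, s$drug_sets, t2, s$catalog)
      expect_true(all(cls[base == "therapeutic"] == "therapeutic"))
    }
  }
})

test_that("degree comparison separates classes and handles identity", {
  th_edges <- expand.grid(d = sprintf("d%d", 1:4), s = sprintf("t%d", 1:4),
                          stringsAsFactors = FALSE)
  edges <- rbind(th_edges,
                 data.frame(d = "d1", s = sprintf("n%d", 1:4)))
  net <- drsn(data.frame(drug_id = edges$d, subpathway_id = edges$s,
                         p_value = 1e-4, stringsAsFactors = FALSE), 0.01)
  cls <- stats::setNames(
    ifelse(startsWith(net$subpathway_nodes, "t"),
           "therapeutic", "non_therapeutic"), net$subpathway_nodes)
  res <- degree_comparison(net, cls)
  expect_lt(res$p_value, 0.1)
  expect_gt(res$medians[["therapeutic"]], res$medians[["non_therapeutic"]])

  same <- toy_drsn(c("d1", "a"), c("d2", "b"), c("d3", "c"), c("d4", "e"))
  cls_same <- c(a = "therapeutic", b = "therapeutic",
                c = "non_therapeutic", e = "non_therapeutic")
  expect_gt(degree_comparison(same, cls_same)$p_value, 0.4)
  expect_error(degree_comparison(same, c(a = "therapeutic", b = "therapeutic")),
               "non-empty")
})

test_that("th_coefficient is the max tissue fraction with deterministic ties", {
  tt <- list(G1 = "liver", G2 = "liver", G3 = "kidney", G4 = "lung")
  res <- th_coefficient(c("G1", "G2", "G3", "G4"), tt)
  expect_equal(res$th, 0.5)
  expect_identical(res$top_tissue, "liver")
  # all in one tissue -> 1; empty -> 0
  expect_equal(th_coefficient(c("G1", "G2"), tt)$th, 1)
  empty <- th_coefficient(character(0), tt)
  expect_equal(empty$th, 0)
  expect_true(is.na(empty$top_tissue))
  # lexicographic tie-break
  tie <- th_coefficient(c("G2", "G3"), tt)
  expect_equal(tie$th, 0.5)
  expect_identical(tie$top_tissue, "kidney")
  expect_error(th_coefficient("G9", tt), "annotation")

  # brute-force oracle over random inputs
  set.seed(17)
  tissues <- sprintf("t%d", 1:6)
  for (rep in 1:25) {
    genes <- sprintf("g%d", 1:8)
    labs <- lapply(genes, function(g)
      sort(sample(tissues, sample(1:3, 1))))
    names(labs) <- genes
    pick <- sample(genes, sample(0:8, 1))
    got <- th_coefficient(pick, labs)
    if (length(pick) == 0) { expect_equal(got$th, 0); next }
    counts <- vapply(tissues, function(t)
      sum(vapply(pick, function(g) t %in% labs[[g]], TRUE)), 0)
    expect_equal(got$th, max(counts) / length(pick))
    best <- sort(tissues[counts == max(counts)])[1]
    expect_identical(got$top_tissue, best)
  }
})

test_that("tissue profiles, composition ratios and TH sums are consistent", {
  catalog <- toy_catalog(list(sp1 = c("G1", "G2", "G3", "G4"),
                              sp2 = c("G5", "G6")))
  net <- toy_drsn(c("dA", "sp1"), c("dB", "sp2"))
  drug_sets <- list(dA = c("G1", "G2", "G3", "G4"), dB = c("G5", "G6"))
  tl <- data.frame(gene_id = c("G1", "G2", "G5", "G6"),
                   label = c("TEG", "HKG", "TEG", "TEG"),
                   tissues = c("liver", "", "liver", "liver"))
  cls <- c(sp1 = "therapeutic", sp2 = "non_therapeutic")
  prof <- subpathway_tissue_profiles(net, drug_sets, catalog, cls, tl)
  expect_equal(prof$teg_ratio[prof$subpathway_id == "sp1"], 0.25)
  expect_equal(prof$hkg_ratio[prof$subpathway_id == "sp1"], 0.25)
  expect_equal(prof$th[prof$subpathway_id == "sp1"], 1)
  expect_equal(prof$th[prof$subpathway_id == "sp2"], 1)

  sums <- tissue_th_sums(prof)
  expect_equal(unname(sums$therapeutic["liver"]), 1)
  expect_equal(unname(sums$non_therapeutic["liver"]), 1)
  # per-class TH mass is conserved by the bucketing
  for (cl in names(sums)) {
    expect_equal(sum(sums[[cl]]), sum(prof$th[prof$class == cl & prof$th > 0]))
  }

  comp <- composition_ratios(rbind(prof, prof))  # need >0 per class
  expect_equal(unname(comp$mean_teg_ratio["therapeutic"]), 0.25)
  expect_equal(unname(comp$mean_hkg_ratio["non_therapeutic"]), 0)

  thc <- th_class_comparison(prof)
  expect_true(thc$p_value > 0 && thc$p_value <= 1)
  expect_error(th_class_comparison(prof[prof$class == "therapeutic", ]),
               "at least one")
})

test_that("planted tissue structure is recovered end to end", {
  # therapeutic subpathways wired to 3x more drugs and TEG-dense:
  # build directly, checking the comparisons point the planted way
  set.seed(23)
  n_th <- 12; n_nth <- 12
  sp_ids <- c(sprintf("th%02d", 1:n_th), sprintf("nt%02d", 1:n_nth))
  gene_sets <- lapply(seq_along(sp_ids), function(i)
    sprintf("g%02d_%d", i, 1:6))
  names(gene_sets) <- sp_ids
  catalog <- toy_catalog(gene_sets)
  edges <- do.call(rbind, lapply(seq_along(sp_ids), function(i) {
    n_drugs <- if (i <= n_th) 6 else 2
    data.frame(drug_id = sprintf("d%02d", sample(30, n_drugs)),
               subpathway_id = sp_ids[i], p_value = 1e-5,
               stringsAsFactors = FALSE)
  }))
  edges <- unique(edges)
  net <- drsn(edges, 0.01)
  drug_sets <- lapply(stats::setNames(nm = sprintf("d%02d", 1:30)), function(d)
    sort(unique(unlist(gene_sets[drug_neighbours(net)[[d]]]))))
  # TEG density double in therapeutic subpathway genes
  all_genes <- unlist(gene_sets)
  teg_p <- ifelse(grepl("^g0[0-9]_|^g1[0-2]_", all_genes), 0.5, 0.25)
  is_teg <- stats::runif(length(all_genes)) < teg_p
  tl <- data.frame(gene_id = all_genes[is_teg], label = "TEG",
                   tissues = sample(c("liver", "kidney", "trachea"),
                                    sum(is_teg), replace = TRUE))
  cls <- stats::setNames(ifelse(startsWith(net$subpathway_nodes, "th"),
                                "therapeutic", "non_therapeutic"),
                         net$subpathway_nodes)
  res <- degree_comparison(net, cls)
  expect_lt(res$p_value, 0.01)
  prof <- subpathway_tissue_profiles(net, drug_sets, catalog, cls, tl)
  comp <- composition_ratios(prof)
  expect_gt(comp$mean_teg_ratio[["therapeutic"]],
            comp$mean_teg_ratio[["non_therapeutic"]])
})
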