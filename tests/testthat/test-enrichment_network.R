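test_that("hypergeometric upper tail matches hand-derived values", {
  expect_equal(hypergeometric_pvalue(0, 5, 5, 10), 1)
  # single-term closed form C(5,5)C(5,0)/C(10,5)
  expect_equal(hypergeometric_pvalue(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # exhaustive sum (100 + 25 + 1)/252
  expect_equal(hypergeometric_pvalue(3, 5, 5, 10), 0.5, tolerance = 1e-12)
  expect_error(hypergeometric_pvalue(6, 5, 5, 10), "inconsistent")
  expect_error(hypergeometric_pvalue(2, 5, 12, 10), "inconsistent")
  # deep tail stays finite and positive
  p <- hypergeometric_pvalue(40, 50, 50, 10000)
  expect_gt(p, 0)
  expect_lt(p, 1e-80)
})

test_that("build_drsn links planted drugs and honours the threshold", {
  cat1 <- toy_catalog(list(sp1 = sprintf("G%02d", 1:10),
                           sp2 = sprintf("G%02d", 11:20)))
  background <- c(sprintf("G%02d", 1:20), sprintf("B%03d", 1:100))
  built <- build_drsn(list(d1 = sprintf("G%02d", 1:10)), cat1, background, 0.01)
  expect_identical(built$network$edges$drug_id, "d1")
  expect_identical(built$network$edges$subpathway_id, "sp1")
  expect_equal(nrow(built$results), 2L)

  # alpha = 1 keeps every tested pair
  all_edges <- build_drsn(list(d1 = sprintf("G%02d", 1:10)), cat1, background, 1)
  expect_equal(nrow(all_edges$network$edges), 2L)

  # permuting inputs leaves the network identical
  sets <- list(d1 = sprintf("G%02d", 1:10), d2 = sprintf("G%02d", 5:14))
  a <- build_drsn(sets, cat1, background, 0.05)$network
  b <- build_drsn(rev(sets), cat1, rev(background), 0.05)$network
  expect_identical(a, b)

  # drugs disjoint from the background are skipped with a warning
  expect_warning(out <- build_drsn(list(dx = "ZZZ"), cat1, background, 0.01),
                 "background")
  expect_equal(nrow(out$results), 0L)
})

test_that("network_stats counts nodes, edges and the giant component", {
  st <- network_stats(toy_drsn(c("d1", "s1"), c("d1", "s2")))
  expect_equal(st$n_nodes, 3L)
  expect_equal(st$n_edges, 2L)
  expect_equal(st$giant_component_size, 3L)

  two_stars <- toy_drsn(c("d1", "s1"), c("d1", "s2"), c("d1", "s3"),
                        c("d2", "s4"), c("d3", "s4"))
  st2 <- network_stats(two_stars)
  expect_equal(st2$giant_component_size, 4L)
  expect_equal(st2$max_drug_degree, 3L)
  expect_equal(st2$max_subpathway_degree, 2L)
  expect_identical(unname(st2$subpathway_degrees[c("s1", "s4")]), c(1L, 2L))
})

test_that("powerlaw_fit recovers an exact constructed power law", {
  degs <- rep(c(1L, 2L, 4L, 8L), c(8L, 4L, 2L, 1L))  # P(k) = c / k
  fit <- suppressWarnings(powerlaw_fit(degs))  # lm warns on the exact fit
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(powerlaw_fit(rep(3L, 10)), "distinct")
  # heavy-tailed degrees give a negative slope
  set.seed(5)
  heavy <- pmax(1L, as.integer(round(stats::rlnorm(300, 0.5, 0.9))))
  expect_lt(powerlaw_fit(heavy)$slope, 0)
})

test_that("randomize_drug_gene preserves degrees for every seed", {
  assoc <- drsn:::drug_sets_to_edges(
    list(d1 = c("g1", "g2", "g3"), d2 = c("g2", "g4"), d3 = c("g1", "g5")))
  expect_identical(randomize_drug_gene(assoc, n_swaps = 0), assoc)
  for (seed in 1:10) {
    sh <- randomize_drug_gene(assoc, seed = seed)
    expect_identical(table(sh$drug_id), table(assoc$drug_id))
    expect_identical(table(sh$gene_id), table(assoc$gene_id))
    expect_false(anyDuplicated(paste(sh$drug_id, sh$gene_id)) > 0)
  }
  # complete bipartite graphs admit no legal swap
  complete <- expand.grid(drug_id = c("a", "b"), gene_id = c("x", "y"),
                          stringsAsFactors = FALSE)
  sh <- randomize_drug_gene(complete, n_swaps = 50, seed = 1)
  expect_identical(sort(paste(sh$drug_id, sh$gene_id)),
                   sort(paste(complete$drug_id, complete$gene_id)))
  # reproducible under seed
  expect_identical(randomize_drug_gene(assoc, seed = 99),
                   randomize_drug_gene(assoc, seed = 99))
})

test_that("null comparison bounds empirical p and detects planted signal", {
  # three drugs, each concentrated on its own subpathway plus private
  # decoys; degree-preserving shuffles spread the subpathway genes across
  # drugs, destroying the concentration
  cat1 <- toy_catalog(list(sp1 = sprintf("G%02d", 1:10),
                           sp2 = sprintf("G%02d", 11:20),
                           sp3 = sprintf("G%02d", 21:30)))
  background <- c(sprintf("G%02d", 1:30), sprintf("B%03d", 1:150))
  sets <- list(d1 = c(sprintf("G%02d", 1:10), sprintf("B%03d", 1:30)),
               d2 = c(sprintf("G%02d", 11:20), sprintf("B%03d", 31:60)),
               d3 = c(sprintf("G%02d", 21:30), sprintf("B%03d", 61:90)))
  res <- null_network_comparison(sets, cat1, background, alpha = 1e-4,
                                 n_random = 19, seed = 2)
  expect_true(all(res$empirical_p >= 1 / 20 & res$empirical_p <= 1))
  # perfectly planted signal beats every shuffle
  expect_equal(unname(res$empirical_p["n_edges"]), 1 / 20)
  expect_equal(unname(res$observed["n_edges"]), 3)
})

test_that("drsn edge tables round-trip", {
  net <- toy_drsn(c("d1", "s1"), c("d2", "s1"), c("d2", "s2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_drsn_edges(net, f)
  expect_identical(read_drsn_edges(f, alpha = 0.01), net)
  expect_identical(drug_neighbours(net)$d2, c("s1", "s2"))
  expect_identical(subpathway_neighbours(net)$s1, c("d1", "d2"))
})
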