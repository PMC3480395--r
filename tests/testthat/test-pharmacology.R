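test_that("connected_drug_pairs counts shared subpathway neighbours", {
  p1 <- connected_drug_pairs(toy_drsn(c("A", "S1"), c("B", "S1")))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$shared_subpathways, 1L)

  net <- toy_drsn(c("A", "S1"), c("A", "S2"), c("B", "S2"), c("B", "S3"),
                  c("C", "S4"))
  p2 <- connected_drug_pairs(net)
  expect_identical(p2$drug_a, "A")
  expect_identical(p2$drug_b, "B")
  expect_equal(p2$shared_subpathways, 1L)
  expect_false("C" %in% c(p2$drug_a, p2$drug_b))

  star <- toy_drsn(c("A", "S"), c("B", "S"), c("C", "S"), c("D", "S"))
  expect_equal(nrow(connected_drug_pairs(star)), choose(4, 2))

  # annotation maps fill shared-term counts; restrict_to filters drugs
  ind <- list(A = c("flu", "cold"), B = "flu")
  p3 <- connected_drug_pairs(net, drug_indication = ind)
  expect_equal(p3$shared_indications, 1L)
  expect_equal(nrow(connected_drug_pairs(star, restrict_to = c("A", "B"))), 1L)
})

test_that("connected_drug_pairs equals a brute-force double loop", {
  set.seed(31)
  for (rep in 1:10) {
    drugs <- sprintf("d%02d", 1:12)
    sps <- sprintf("s%02d", 1:8)
    edges <- expand.grid(drug_id = drugs, subpathway_id = sps,
                         stringsAsFactors = FALSE)
    edges <- edges[stats::runif(nrow(edges)) < 0.2, ]
    if (nrow(edges) < 2) next
    net <- drsn(cbind(edges, p_value = 1e-4), 0.01)
    got <- connected_drug_pairs(net)
    nb <- drsn::drug_neighbours(net)
    expected <- list()
    ds <- sort(names(nb))
    for (i in seq_along(ds)) for (j in seq_along(ds)) {
      if (i >= j) next
      shared <- length(intersect(nb[[ds[i]]], nb[[ds[j]]]))
      if (shared > 0) {
        expected[[paste(ds[i], ds[j])]] <- shared
      }
    }
    expect_identical(paste(got$drug_a, got$drug_b), names(expected))
    expect_identical(got$shared_subpathways, unname(unlist(expected)))
  }
})

test_that("strict exceedance counting is the permutation p-value", {
  ep <- empirical_p_strict(67, c(rep(70, 36), rep(60, 964)))
  expect_identical(ep$exceedances, 36L)
  expect_identical(ep$empirical_p, 0.036)
  # ties do not count as exceedances
  expect_identical(empirical_p_strict(5, c(5, 5, 6))$exceedances, 1L)
})

test_that("shared_indication_test counts sharing pairs against random draws", {
  net <- toy_drsn(c("A", "S1"), c("B", "S1"), c("C", "S1"), c("D", "S2"),
                  c("E", "S2"))
  ind <- list(A = "flu", B = "flu", C = "cold", D = "ache", E = "ache")
  pairs <- connected_drug_pairs(net, drug_indication = ind)
  res <- shared_indication_test(pairs, ind, names(ind), n_perm = 200, seed = 4)
  expect_equal(res$observed_count, 2L)  # (A,B) and (D,E)
  expect_equal(res$n_pairs, 4L)
  expect_identical(res$empirical_p, res$exceedances / 200)
  expect_true(res$empirical_p >= 0 && res$empirical_p <= 1)

  # degenerate ceiling: everyone shares everything, nothing can exceed
  same <- stats::setNames(rep(list("flu"), 5), c("A", "B", "C", "D", "E"))
  pairs2 <- connected_drug_pairs(net, drug_indication = same)
  res2 <- shared_indication_test(pairs2, same, names(same), n_perm = 50, seed = 1)
  expect_equal(res2$observed_count, nrow(pairs2))
  expect_identical(res2$empirical_p, 0)

  # invariant to drug relabeling
  relabel <- c(A = "z1", B = "z2", C = "z3", D = "z4", E = "z5")
  net_r <- toy_drsn(c("z1", "S1"), c("z2", "S1"), c("z3", "S1"),
                    c("z4", "S2"), c("z5", "S2"))
  ind_r <- stats::setNames(ind, relabel[names(ind)])
  pairs_r <- connected_drug_pairs(net_r, drug_indication = ind_r)
  res_r <- shared_indication_test(pairs_r, ind_r, names(ind_r),
                                  n_perm = 200, seed = 4)
  expect_identical(res_r$observed_count, res$observed_count)
  expect_identical(res_r$empirical_p, res$empirical_p)

  expect_error(shared_indication_test(pairs, ind, "A", 10, 1), "at least 2")
})

test_that("side-effect comparison separates planted sharing", {
  net <- toy_drsn(c("A", "S1"), c("B", "S1"), c("C", "S2"), c("D", "S3"))
  se <- list(A = sprintf("t%d", 1:5), B = sprintf("t%d", 1:5),
             C = "u1", D = "u2")
  pairs <- connected_drug_pairs(net, drug_side_effects = se)
  res <- shared_side_effect_comparison(pairs, se)
  expect_identical(res$connected_counts, 5L)
  expect_equal(length(res$background_counts), choose(4, 2))
  expect_lt(res$p_value, 0.2)
  expect_gt(res$connected_mean, res$background_mean)
  expect_error(shared_side_effect_comparison(pairs, list(A = "x")), "at least 2")
})

test_that("trend regression fits binned means of shared side effects", {
  pairs <- data.frame(drug_a = letters[1:6], drug_b = LETTERS[1:6],
                      shared_subpathways = c(1, 1, 2, 2, 3, 3),
                      shared_indications = 0,
                      shared_side_effects = c(1.5, 2.5, 3.6, 4.6, 5.5, 6.5))
  res <- shared_subpathway_trend(pairs)
  expect_equal(res$bin_means, c(2, 4.1, 6))
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_lt(res$slope_p, 0.05)

  flat <- pairs; flat$shared_side_effects <- 3
  expect_equal(suppressWarnings(shared_subpathway_trend(flat)$slope), 0,
               tolerance = 1e-10)

  raw <- shared_subpathway_trend(pairs, raw = TRUE)
  expect_equal(raw$slope, 2, tolerance = 1e-10)

  few <- pairs[pairs$shared_subpathways < 3, ]
  expect_error(shared_subpathway_trend(few), "3 distinct")
})
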