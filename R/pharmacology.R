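#' Connected drug pairs of a DRSN
#'
#' Two drugs form a connected pair when they are linked to at least one
#' common subpathway. One record is returned per unordered pair
#' (`drug_a < drug_b`), with the number of shared subpathway neighbours
#' and, when annotation maps are supplied, the number of shared indication
#' and side-effect terms.
#'
#' @param net a [drsn].
#' @param restrict_to optional character vector; only drugs in this set
#'   (e.g. drugs with annotation records) enter pairs.
#' @param drug_indication,drug_side_effects optional named lists of
#'   per-drug term vectors used to fill the shared-term counts
#'   (`NA` when absent).
#' @return data.frame with columns `drug_a`, `drug_b`,
#'   `shared_subpathways`, `shared_indications`, `shared_side_effects`.
#' @export
connected_drug_pairs <- function(net, restrict_to = NULL,
                                 drug_indication = NULL,
                                 drug_side_effects = NULL) {
  nb <- drug_neighbours(net)
  if (!is.null(restrict_to)) nb <- nb[names(nb) %in% restrict_to]
  drugs <- sort(names(nb))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (sp_drugs in subpathway_neighbours(net)) {
    sp_drugs <- sort(intersect(sp_drugs, drugs))
    if (length(sp_drugs) < 2L) next
    for (i in seq_len(length(sp_drugs) - 1L)) {
      for (j in (i + 1L):length(sp_drugs)) {
        k <- paste0(sp_drugs[[i]], "\r", sp_drugs[[j]])
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      }
    }
  }
  keys <- sort(ls(counts))
  if (length(keys) == 0L) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      shared_subpathways = integer(0),
                      shared_indications = integer(0),
                      shared_side_effects = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  shared_terms <- function(map, a, b) {
    if (is.null(map)) return(NA_integer_)
    length(intersect(map[[a]], map[[b]]))
  }
  data.frame(
    drug_a = parts[, 1L], drug_b = parts[, 2L],
    shared_subpathways = vapply(keys, function(k) counts[[k]], 0L,
                                USE.NAMES = FALSE),
    shared_indications = mapply(shared_terms, a = parts[, 1L], b = parts[, 2L],
                                MoreArgs = list(map = drug_indication),
                                USE.NAMES = FALSE),
    shared_side_effects = mapply(shared_terms, a = parts[, 1L], b = parts[, 2L],
                                 MoreArgs = list(map = drug_side_effects),
                                 USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Empirical p-value from strict exceedance counts
#'
#' The counting contract of the indication permutation test: the p-value is
#' the fraction of permutations whose statistic strictly exceeds the
#' observed one (e.g. 36 of 1000 permutations beating an observed count of
#' 67 gives p = 0.036).
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of permutation statistics.
#' @return list with `exceedances` and `empirical_p`.
#' @export
empirical_p_strict <- function(observed, null_values) {
  exceed <- sum(null_values > observed)
  list(exceedances = exceed, empirical_p = exceed / length(null_values))
}

#' Permutation test for shared indications among connected drug pairs
#'
#' Counts the connected drug pairs sharing at least one indication, then
#' compares against `n_perm` draws of the same number of uniform random
#' unordered drug pairs (without replacement within a draw) from the given
#' drug universe. The p-value is the strict exceedance fraction.
#'
#' @param pairs data.frame from [connected_drug_pairs] (only pairs whose
#'   both drugs have indication records are counted).
#' @param drug_indication named list: drug id -> indication terms.
#' @param universe character vector of drugs to draw random pairs from
#'   (conventionally: network drugs with indication records).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `observed_count`, `n_pairs`, `null_mean`,
#'   `exceedances`, `empirical_p`.
#' @export
shared_indication_test <- function(pairs, drug_indication, universe,
                                   n_perm = 1000L, seed = 1L) {
  universe <- sort(unique(universe))
  if (length(universe) < 2L) stop("drug universe must contain at least 2 drugs")
  stopifnot(n_perm >= 1)
  keep <- pairs$drug_a %in% universe & pairs$drug_b %in% universe
  pairs <- pairs[keep, , drop = FALSE]
  shares <- function(a, b) {
    length(intersect(drug_indication[[a]], drug_indication[[b]])) > 0L
  }
  observed <- sum(mapply(shares, pairs$drug_a, pairs$drug_b))
  n_pairs <- nrow(pairs)
  # indicator of sharing over all unordered universe pairs, sampled per draw
  idx <- utils::combn(length(universe), 2L)
  share_ind <- mapply(function(i, j) shares(universe[[i]], universe[[j]]),
                      idx[1L, ], idx[2L, ])
  if (n_pairs > length(share_ind)) {
    stop("more connected pairs than available universe pairs")
  }
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(b) {
    sum(share_ind[sample.int(length(share_ind), n_pairs)])
  }, 0L)
  ep <- empirical_p_strict(observed, null_counts)
  list(observed_count = observed, n_pairs = n_pairs,
       null_mean = mean(null_counts), exceedances = ep$exceedances,
       empirical_p = ep$empirical_p)
}

#' Shared side effects: connected pairs vs all annotated pairs
#'
#' Compares the numbers of side-effect terms shared by connected drug
#' pairs against the numbers shared by all unordered pairs of annotated
#' drugs, with a one-sided ("greater") Wilcoxon rank-sum test. Counting
#' shared terms per pair (rather than whether any term is shared) keeps
#' ubiquitous side effects from dominating the comparison.
#'
#' @param pairs data.frame from [connected_drug_pairs].
#' @param drug_side_effects named list: drug id -> side-effect terms.
#' @param all_drugs drugs defining the background pair universe
#'   (default: all drugs with side-effect records).
#' @return list with `connected_counts`, `background_counts`, `statistic`,
#'   `p_value`, and the two means.
#' @export
shared_side_effect_comparison <- function(pairs, drug_side_effects,
                                          all_drugs = names(drug_side_effects)) {
  all_drugs <- sort(unique(all_drugs))
  if (length(all_drugs) < 2L) stop("need at least 2 annotated drugs")
  keep <- pairs$drug_a %in% all_drugs & pairs$drug_b %in% all_drugs
  pairs <- pairs[keep, , drop = FALSE]
  nshared <- function(a, b) length(intersect(drug_side_effects[[a]],
                                             drug_side_effects[[b]]))
  connected <- mapply(nshared, pairs$drug_a, pairs$drug_b, USE.NAMES = FALSE)
  idx <- utils::combn(length(all_drugs), 2L)
  background <- mapply(function(i, j) nshared(all_drugs[[i]], all_drugs[[j]]),
                       idx[1L, ], idx[2L, ])
  if (length(connected) == 0L || length(background) == 0L) {
    stop("both pair samples must be non-empty")
  }
  wt <- stats::wilcox.test(connected, background, alternative = "greater",
                           exact = FALSE)
  list(connected_counts = as.integer(connected),
       background_counts = as.integer(background),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       connected_mean = mean(connected), background_mean = mean(background))
}

#' Trend of shared side effects against shared subpathways
#'
#' Bins connected pairs by their exact shared-subpathway count, averages
#' the shared side-effect counts within each bin, and fits an ordinary
#' least-squares line of bin mean on bin value; the slope's two-sided
#' t-test assesses whether sharing more subpathways goes with sharing more
#' side effects. Set `raw = TRUE` to regress on unbinned pairs instead.
#'
#' @param pairs data.frame from [connected_drug_pairs], with
#'   `shared_side_effects` filled in.
#' @param raw regress on raw pairs rather than binned means.
#' @return list with `bin_values`, `bin_means`, `slope`, `slope_p`.
#' @export
shared_subpathway_trend <- function(pairs, raw = FALSE) {
  pairs <- pairs[!is.na(pairs$shared_side_effects), , drop = FALSE]
  if (length(unique(pairs$shared_subpathways)) < 3L) {
    stop("need at least 3 distinct shared-subpathway values")
  }
  if (raw) {
    fit <- stats::lm(shared_side_effects ~ shared_subpathways, data = pairs)
    x <- sort(unique(pairs$shared_subpathways))
    means <- tapply(pairs$shared_side_effects, pairs$shared_subpathways, mean)
  } else {
    means <- tapply(pairs$shared_side_effects, pairs$shared_subpathways, mean)
    x <- as.numeric(names(means))
    fit <- stats::lm(as.numeric(means) ~ x)
  }
  sm <- summary(fit)$coefficients
  list(bin_values = as.numeric(names(means)), bin_means = unname(as.numeric(means)),
       slope = unname(stats::coef(fit)[[2L]]),
       slope_p = if (nrow(sm) >= 2L) sm[2L, 4L] else NA_real_)
}
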