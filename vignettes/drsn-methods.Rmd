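---
title: "Drug–metabolic subpathway networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug–metabolic subpathway networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsn)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## The model

### Subpathways as distance-bounded cliques

A metabolic pathway is represented as an undirected graph over enzyme
nodes, each node annotated with one or more genes. A **subpathway** is a
maximal set of nodes whose pairwise shortest-path distance within the
pathway is at most `k`. These sets are exactly the maximal cliques of the
distance-`k` power graph, so mining reduces to exact maximal-clique
enumeration (pivoting Bron–Kerbosch, via igraph), which is comfortably
fast at metabolic-pathway sizes (tens of nodes). Determinism: subpathways
are ordered lexicographically by sorted node list, and ids
`"<pathway>_<n>"` are assigned in that order.

*Parameters.* `k` (default 3, dimensionless graph distance): small `k`
keeps enzymes within a subpathway functionally close; `k = 4` is supported
as a robustness setting. `min_size` (default 2 nodes): singleton
"subpathways" carry no interaction information; the threshold is
configurable because the original method leaves it unstated.

*Assumptions.* Edges are undirected — the distance criterion is stated
without direction, so directed relations are collapsed. Multi-gene nodes
contribute all their genes to a subpathway's gene set; this flattening is
our convention (how the original tooling flattened multi-enzyme nodes is
not documented). Subpathways identical in gene content but different in
node content are both kept: node identity is primary.

### Differential expression and drug gene sets

Per paired instance, gene `g` is differentially expressed when
`|log2((t_g + c)/(c_g + c))| > tau`, with `tau = 1` (two-fold) and
pseudocount `c = 1` intensity unit. The threshold is strict; down- and
up-regulation count equally; and the pseudocount guards zero denominators
while being negligible at array-scale intensities (baselines around
`2^7`). The source material states the bound both as a log2 bound and as a
raw fold-change bound of 1; the latter is vacuous, so the log2 form is
implemented and the threshold is a parameter. Per drug, instance DEG sets
are unioned — no replicate averaging within an instance, no cell-line
stratification (instances are pooled per drug).

### Enrichment and network assembly

Drug set vs subpathway set is tested with the exact upper-tail
hypergeometric probability, summed term by term in log space
(`lchoose` + log-sum-exp), after intersecting both sets with the
background. The **background** is the union of all pathway-annotated genes
by default (`"universe"` — all measured genes — is available): enrichment
against the pathway-annotated universe is the convention of subpathway
enrichment tools, and the choice is configurable because it is otherwise
unstated. The test is one-sided (over-representation only), with no
multiple-testing correction by default, honouring the raw `p < 0.01` rule
of the original analysis; edges exist iff `p_value < alpha`, with
`alpha = 1` treated as the degenerate keep-everything boundary (a strict
inequality would exclude `p = 1` pairs, contradicting the boundary's
intent). Nodes without a significant edge are not part of the network.

The null model shuffles the *drug–gene* associations with degree-
preserving edge swaps (both each drug's gene count and each gene's drug
count fixed), then re-runs the entire enrichment per replicate —
network-level statistics require rebuilt networks. `n_swaps` defaults to
`10 × |edges|`, the standard mixing heuristic for edge-swap MCMC.
Empirical p-values here use the add-one estimator
`(1 + #exceed) / (1 + n)`, bounded away from zero; raw exceedance counts
are reported alongside, so a "p = 0"-style claim can be read off without
an unbounded estimator.

The log–log degree-distribution fit (`powerlaw_fit`) is an ordinary
least-squares line through `(log10 k, log10 P(k))` over observed degrees.
Whether the original analysis fit the PDF or CCDF, raw or binned, is
unstated; the fit is therefore descriptive only and its slopes are not
asserted anywhere.

### Drug-pair pharmacology

Connected drug pairs share at least one subpathway neighbour;
`shared_subpathways` is the neighbour-set intersection size. The
indication test draws, per permutation, the same number of unordered drug
pairs *without replacement within a draw* from the annotated-drug
universe, and reports the strict exceedance fraction
(`#{null > observed}/n_perm`) — strict, matching the source's "more than"
counting. The side-effect comparison counts shared *terms* per pair
(not binary sharing, which ubiquitous side effects would saturate) and
uses a one-sided Wilcoxon rank-sum test against all unordered annotated
pairs; the background universe defaults to the annotated drugs handed to
the operation, since whether the original background was all resource
drugs or the network ∩ resource subset is ambiguous — both are reachable
via the `all_drugs` argument. The trend of shared side effects on shared
subpathways is fit on binned means (as the original figure describes);
raw-pair regression is available via `raw = TRUE`.

### Drug–disease association scores

For drug `s` and disease `t`, `FER = O / E` with `O` the shared
subpathway count and `E = |S_s| |S_t| / U`. The class-level score is

```
AS(i, j) = (1 / (N_i N_j)) * sum over s in class i, t in class j of FER(s, t)
```

with `U` computed **per class pair**: the number of distinct subpathways
linked to any drug of class `i` or any disease of class `j`. The exact
algebraic form of the original AS was not recoverable from the source
(the formula figure is unreadable); this class-size-normalised double sum
is the only natural reading that uses `N_i` and `N_j` as defined, and it
is recorded prominently as an assumption. Consequences tested: duplicating
a class's drugs leaves AS unchanged (mean normalisation); AS = 0 iff no
pair shares a subpathway. Pair-level overlap significance is upper-tail
hypergeometric with the population equal to all mined subpathways at the
chosen `k`; pairs with `p < 0.01` are flagged. Empty classes are reported
absent, not zero.

### Tissue specificity

A network subpathway is **therapeutic** when some linked drug's *own*
therapeutic target lies among that drug's affected genes inside the
subpathway — drug-specific by default, because "these therapeutic
targets" most plausibly refers back to the linked drugs' targets; the
pooled-target reading is available via `global_targets = TRUE` since the
sentence is genuinely ambiguous. Affected genes per subpathway are the
union over linked drugs (ratios are reported per subpathway, not per
drug–subpathway pair). The tissue-homogeneity coefficient is
`TH = max_j n_ij / n_i` over tissues `j`, where `n_i` counts the
subpathway's drug-affected tissue-specific genes (TEGs) and `n_ij` those
expressed in tissue `j`; a multi-tissue TEG counts once per tissue; ties
break lexicographically for determinism; `TH = 0` with no top tissue when
there are no TEGs. Per-tissue TH sums bucket each subpathway's TH into its
top tissue within its class, so per-class TH mass is conserved — an
invariant the tests check. Class comparisons are Wilcoxon rank-sum tests
(one-sided where the scientific claim is directional, two-sided for HKG
ratios); "all subpathways" comparisons include both classes.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
not any real resource. Stated defaults (see `simulation_config`):

| parameter | default | why |
|---|---|---|
| pathways | 10 of 8–14 nodes | metabolic-map scale, mineable at k = 3 |
| edge density | 0.15 extra-edge prob. over a spanning tree | sparse but connected enzyme graphs |
| genes per node | 1–3 | KEGG enzyme nodes map to one or a few genes |
| decoy genes | 100 | measured genes outside any pathway |
| drugs | 30, 1–3 instances each | small CMap-like design |
| planted effect | log2 effect 2 on 2 subpathways/drug | clear four-fold signal |
| noise | per-arm log-normal, sd 0.3 (log2) | moderate array noise |
| background DEG rate | 0.01 | occasional off-target perturbation |
| baseline intensity | log-normal, log2 mean 7, sd 1 | array-like intensities |
| classes | 4 drug × 4 disease, matched blocks | planted AS structure |
| side effects | vocab 50; sharing 0.3 on anchor subpathways vs 0.02 baseline | co-linked drugs share terms |
| indications | vocab 20 in class blocks (0.7 within, 0.05 background) | class-structured, network-independent |
| tissue labels | 15% HKG, 25% TEG over 10 tissues | HKG/TEG-style composition at gene-set scale |
| therapeutic targets | rate 0.02 over planted genes | about one target per 1–2 drugs, the scale of curated target resources |

Ground truth (drug → planted subpathways) is emitted as a first-class
artifact, so recovery tests never reverse-engineer the generator. The
whole chain is deterministic under `seed` (stages use `seed`, `seed + 1`,
`seed + 2`).

**What a green test does not establish.** The generator does not emulate
real pathway topology, rank-normalised expression distributions,
correlated instances, name-matching noise, or targets outside metabolic
pathways. That last point matters: because targets are sampled from
planted subpathway genes (the stated mechanism), dense small catalogs
classify most network subpathways as therapeutic — the real-world
minority-therapeutic split arises from targets that metabolic subpathways
never contain, which this world cannot produce. Published headline
numbers (743 subpathways at k = 3, 3925 edges, ratio means 0.14/0.065,
power-law slopes) depend on the real resources and are deliberately not
reproduced or asserted.

## Numerical choices and degenerate inputs

- Hypergeometric tails are exact log-space sums; an acceptance test checks
  agreement with rational arithmetic (Python `fractions`) to 12
  significant digits for `N ≤ 60`.
- Strict inequalities throughout where the source counts strictly
  (DEG threshold, permutation exceedances, edge significance).
- The permutation p (`exceedances/n_perm`) can be 0 (degenerate ceiling);
  the null-network empirical p uses add-one and cannot be.
- A discrete upper-tail test has attainable size below nominal `alpha`;
  with coarse overlap grids the null edge count sits visibly below
  `alpha × tests`. The calibration test uses set sizes giving a fine
  grid (mean null overlap ≈ 12) so realized size approaches nominal.
  Similarly, the strict-exceedance permutation p is anti-conservative
  under heavy ties; calibration is checked at the published scale
  (160 drugs, 1586 pairs), where the statistic's support is fine enough
  for the type-I error to sit near 0.05.
- Degenerate inputs: empty annotation tables parse to empty maps; drugs
  disjoint from the background are skipped with a warning; subpathways
  with no affected genes are excluded from ratio comparisons;
  `powerlaw_fit` and the trend regression refuse fewer than three
  distinct values; TH tie-breaks are lexicographic.

## Known limitations

- The AS formula is a reconstruction (above); a different published
  algebraic form would change score magnitudes, though not the planted
  block-recovery behaviour the tests rely on.
- `validate_drsn_file` reproduces published network statistics only when
  given the published edge table, which must be supplied by the user; no
  downloading is attempted.
- The CLI covers `all` and `validate-s2`; individual stages are exposed
  as documented R functions rather than separate subcommands.
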