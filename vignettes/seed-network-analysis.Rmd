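---
title: "Seed-based PPI network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based PPI network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

seednet implements the analytical core of seed-based protein--protein
interaction (PPI) network analysis as a scriptable library: identify genes of
interest from expression data, map them onto an interactome, build and refine
a subnetwork, and interrogate it with topology, module and enrichment
analyses. This vignette documents the models behind each step, the tunable
parameters, the design decisions that were genuinely open, and what the
synthetic validation does and does not establish.

## The interactome and identifier mapping

The interaction universe is a user-supplied, tab-delimited edge list of
undirected binary interactions. PPI graphs are treated as simple undirected
graphs: self-interactions and duplicate pairs (in either orientation) are
dropped at load time, with counts logged. Interactions are unweighted and
equal; confidence scores, if present in a source database, are not consumed.

Identifier translation is delegated to one optional two-column mapping table
(external ID → canonical ID) rather than bundled platform annotation tables,
which removes all external-database dependence. Comparison is case-sensitive
after whitespace trimming: this is deterministic and documentable, whereas
case-folding silently merges distinct identifiers in some nomenclatures. The
mapping always contains the identity over the interactome's own proteins, so
`map_ids()` is idempotent on canonical IDs.

## Expression processing and seed selection

Expression matrices arrive in a tab-delimited format with features in rows,
samples in columns, and one experimental factor per row beginning `#CLASS`
(e.g. `#CLASS:disease`, `#CLASS:time`). Probes mapping to the same gene are
collapsed to their per-sample arithmetic mean. Normalization is
`log2(x)` for intensity data and `log2((count + 0.5) / (library_size + 1) *
1e6)` (log2 counts per million) for counts; the pseudocount of 0.5 and the
+1 on the column-sum library size avoid `log(0)` and make the formula exact
and testable. Intensity data with a maximum below 30 are assumed to be
already log-scaled and are left untouched — a common-practice heuristic,
overridable with `force_log = TRUE`.

Differential expression uses an ordinary pooled-variance linear model: for a
two-group comparison, `logFC = mean(group_b) - mean(group_a)` on the log2
scale and a two-sided t statistic with `n_a + n_b - 2` degrees of freedom;
one-way multi-group factors get the classical equal-variance ANOVA F. The
sign convention (second group minus first) is fixed and exposed through the
interface, since either convention is defensible. Moderated (empirical
Bayes) statistics and complex designs — paired, block, time-series,
common-control, nested — are deliberately out of scope; the simplest
standard model keeps every number reproducible by hand. Missing values are
ignored per gene; a gene is dropped from a comparison when any group retains
fewer than two observed values, and a zero pooled variance with nonzero
logFC reports the smallest representable p with a logged warning. Multiple
testing uses Benjamini--Hochberg step-up (no procedure is canonical here;
BH is the field default and both raw and adjusted values are reported).

Seeds are genes passing a combined cutoff, `p ≤ p_cutoff` and `|logFC| ≥
fc_cutoff` (defaults 0.05 and 1 on the adjusted p). In meta-analysis mode,
`merge_seed_sets()` replaces per-gene fold changes with the number of
datasets in which the gene was significant.

## Network construction

With mapped seeds `S` and interactome graph `G`:

* **zero order** — the induced subgraph of `G` on `S`, for very large seed
  lists;
* **first order** — the induced subgraph on `S` plus all direct interactors
  of `S`, the default network;
* **expansion** — first-order construction re-run with every current node
  as a seed, incrementing the order tag, for very small networks.

The induced-subgraph rule (all interactome edges among member nodes, not
only seed--interactor edges) is used throughout: module structure and
topology are meaningless on a graph whose interactor--interactor edges have
been discarded. Seeds that map into the interactome but have no qualifying
edges are kept as singleton nodes — silently vanishing seeds are worse than
visible isolated ones.

Trimming "to the nodes that connect the seeds" is formalized as the union
of all shortest paths (unit edge lengths, computed within the current
network) between seed pairs: a non-seed node `v` survives iff
`d(s,v) + d(v,t) = d(s,t)` for some seed pair `(s,t)`. This is
deterministic and polynomial, and never disconnects a seed pair that was
connected. Exact Steiner-tree minimization would be NP-hard and its result
non-unique, so it was rejected.

Connected components are reported largest-first (the "continent", then the
"islands"), with ties broken by the lexicographically smallest member so
output order is reproducible. Node-count guidance (200--2000 recommended;
above 5000 strongly discouraged) is advisory only — messages, never errors.

## Topology

Degree is the incident-edge count. Betweenness centrality is the standard
unnormalized fractional count: `B(v) = Σ_{s<t, v∉{s,t}} σ_st(v)/σ_st`,
where `σ_st` is the number of shortest `s`--`t` paths. When shortest paths
tie, fractional counting is the standard resolution and is the one
implemented; the efficient (Brandes-type) computation is validated exactly
against an exhaustive shortest-path enumeration oracle on random graphs.
Hub tables render a dash for non-seed expression values. Path Explorer
enumerates *all* distinct shortest paths between two nodes, in
lexicographic order with a cap.

## Module detection

Modules are found with the Walktrap algorithm: short random walks of length
`t` define a walk distance between vertices, singleton modules are merged
bottom-up Ward-style, and the partition is taken at the merge-tree cut
maximizing weighted modularity. `t = 4` by default — the walk length its
authors recommend — and exposed as `steps`.

The random walk runs on an expression-weighted graph. For adjacent nodes
with absolute log fold changes `|fc_i|`, `|fc_j|` (0 for non-seeds), the
edge weight is

```
w_ij = baseline + ((|fc_i| + |fc_j|) / 2)^2
```

i.e. the square of the mean absolute log fold change of the two endpoints,
plus a strictly positive baseline (default 1). Without the baseline every
edge between two non-seed nodes would have weight 0 and the walk's
transition probabilities would be undefined on exactly the nodes that make
up most of a first-order network. With all fold changes 0 the weights are
uniform and the procedure reduces to unweighted Walktrap (a property the
test suite checks). The baseline is switchable for sensitivity analysis.

Module significance tests whether a module is denser inside than out: for
each member node, its internal degree (edges to module members) and
external degree (edges to the rest) are recorded; the two resulting
samples are compared with a one-sided Wilcoxon rank-sum test for
internal > external. "Comparing within-module edges against
boundary edges" admits several formalizations; the per-node reading is the
one that yields two comparable samples of equal size, which a rank-sum
test requires. Degree data are small counts with heavy ties, so
`stats::wilcox.test`'s exact branch is unavailable; the exact conditional
permutation distribution under ties is computed by a subset-sum dynamic
program over doubled midranks whenever both samples have ≤ 25 values (an
isolated 4-clique in an 8-node network gives exactly p = 1/70), and the
tie-corrected normal approximation with continuity correction is used
above that. Detection runs per connected component; singleton components
become their own modules but are excluded from testing, as is a module
equal to the whole network (the test is undefined there). Raw p-values are
reported without cross-module correction, which is noted in the output
docs. Modules are ranked by seed count, then smaller p, then larger size,
then lexicographic first member, and each carries the mean |logFC| of its
member seeds.

## Enrichment

Function analysis is hypergeometric over-representation: for a term with
`K` members in a universe of `N` genes and an effective selection of `n`
genes overlapping the term in `k`, the p-value is the inclusive upper tail
`P(X ≥ k)`; `k = 0` gives p = 1, and BH adjustment runs across terms.
Under-representation and ranked (GSEA-style) tests are out of scope. The
universe is the union of the collection's members intersected with the
interactome — the genes that could actually have been selected from a
network — switchable to all interactome proteins. Gene sets use the
standard GMT format; no GO/KEGG/Reactome data are bundled.

## Synthetic data: what it emulates, and what it does not

The generators define the fixed conditions under which the package
validates itself:

* `simulate_ppi()` — preferential attachment (default 500 nodes, `m = 3`
  edges per new node, exactly `(n-m)·m` edges), mimicking the hub-dominated
  degree distribution of curated interactomes, where proteins average on
  the order of ten partners.
* `simulate_communities()` — a stochastic block model, default 4 blocks ×
  20 nodes with `p_in = 0.3`, `p_out = 0.02`, used to score community
  recovery against known labels by adjusted Rand index (mean ≥ 0.9 over 20
  replicates).
* `simulate_expression()` — i.i.d. Gaussian noise around a log2 baseline
  of 8; the planted-effect condition is 50 of 1000 genes shifted by 2.0
  with σ = 0.5 at 10 + 10 samples (1000 genes being a realistic filtered
  array size), the null-calibration condition 10,000 genes at 5 + 5, σ = 1.
* `simulate_gmt()` — random term memberships, optionally one planted term
  constructed as a superset of a given selection.

All generators are byte-deterministic under a fixed seed, and their outputs
re-parse losslessly through the corresponding readers.

Real data differ in ways these generators deliberately do not model:
correlated gene expression, heteroscedastic and heavy-tailed noise, batch
effects, false-positive and condition-dependent interactions, and
overlapping or nested biological modules. Passing the synthetic suite
therefore establishes the *correctness of the computations* under known
truth — not that any biological conclusion drawn from a real dataset is
right.

## Numerical and degenerate-input choices

* Ties in every ranking (hubs, components, modules, paths) break
  lexicographically by node ID, so outputs are stable across runs and
  platforms.
* Identical groups give `logFC = 0`, `p = 1` rather than 0/0.
* Empty seed selections warn rather than error; zero mapped seeds at
  network construction is a hard error ("no seeds in interactome").
* Exact vs approximate Wilcoxon switches at sample size 25; subset counts
  in the exact branch stay below 2^53, so the dynamic program is exact in
  double precision.
* The GraphML writer declares each attribute key once, omits the
  expression attribute for nodes lacking a value, writes doubles with 15
  significant digits, and round-trips networks exactly.
* Session files are versioned JSON; a missing or unknown version is an
  explicit error.

## Validation problem sizes

The test suite and the acceptance script validate: betweenness against
exhaustive enumeration on 30 random graphs of ≤ 12 nodes; the barbell of
two 5-cliques against exhaustive modularity search over all 115,975
partitions of 10 nodes; hypergeometric tails against direct summation on
200 random parameter tuples; the exact Wilcoxon branch against full
permutation enumeration for samples ≤ 8; construction invariants on 100
random interactome/seed instances; and the full pipeline on a 300-protein
synthetic interactome with 200 genes, 8 + 8 samples and a planted gene-set
term, which must rank first by enrichment p.

## Known limitations

Two-group and one-way multi-group comparisons only; no moderated
statistics; no batch correction. The trimming rule is a shortest-path
relaxation, not a minimum Steiner tree. Module p-values are not corrected
across modules. Interaction confidence weighting and visualization
(layouts, rendering) are out of scope — GraphML export is the interchange
point for visualization tools.
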