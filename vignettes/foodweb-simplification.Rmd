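---
title: "Taxonomic simplification of food webs: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomic simplification of food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodweblump)
```

## The problem

Building a food web at full species resolution is expensive: every node
must be identified, and every trophic link recorded. A pragmatic
alternative is to lump nodes by taxonomy — replace species by their genus,
family, or coarser rank — and ask how much of the network's topological
signal survives. `foodweblump` implements that programme: it lumps directed
prey-to-predator webs across an ordered series of resolution levels,
recomputes node-level and global indices at each level, and quantifies how
well community structure in the simplified web agrees with the original.

A food web here is a directed graph whose edges run from prey to predator,
following the energy flow. Edge weights are interaction strengths; an
unweighted source materialises weight 1 per interaction record, so weights
always sum to the number of records behind them.

## The simplification operator

Given a taxonomy table (ranked lineage per taxon, possibly ragged) and a
scheme (per group key, the target rank at each named level), every node is
mapped to its lineage value at the target rank and edges are merged by
summing weights over each ordered group pair. Three conventions matter:

* **Weight conservation.** The total edge weight is invariant at every
  level. This holds because merging only reassigns edge endpoints; it is
  the invariant every property test pins down.
* **Self-loops are retained.** Lumping can place a predator and its prey
  in the same group. We keep the resulting self-loop and report its count,
  because it is a diagnostic of over-simplification, not noise. Dropping
  self-loops is available as an explicit flag, at the cost of weight
  conservation.
* **Nestedness.** A scheme must be rank-monotone within each group key
  (never finer at a coarser level). Under that constraint, simplifying the
  raw web directly to any level equals cascading through the intermediate
  levels; the test suite verifies this by lifting the taxonomy onto group
  labels and re-simplifying.

Ragged lineages are resolved by falling back to the nearest *present* rank
coarser than the target, and finally to the taxon's own label. Taxa absent
from the taxonomy follow a policy: `passthrough` (default — undetermined
entities stay visible under their own name), `strict` (error), or
`group-label` (use the vernacular group column, which is also how
"common word" groupings such as `Beetles_water` are expressed, via literal
labels in the scheme). A rank-derived label shared by lineages from
different phyla (homonym genera exist) is disambiguated by suffixing the
phylum, because label-keyed graphs must never silently merge unrelated
taxa.

## Indices and their conventions

All node indices are reported raw and min–max normalized,
$x' = (x - \min x)/(\max x - \min x)$, so webs of different size can be
overlaid. When all values are equal the normalization is undefined; we map
the vector to 0 to keep outputs in $[0, 1]$. The normalization is
order-preserving and invariant to positive affine transforms (tested).

* **Average degree is E/n**, the mean number of edges per node — not the
  textbook mean total degree $2E/n$. This is the convention under which a
  71-node, 148-edge web summarises to 2.08, and it is locked by a
  regression test because the ambiguity is real.
* **Density** is $E/(n(n-1))$, the realized fraction of possible directed
  links; undefined (reported `NA`, never 0) below two nodes.
* **Degree centrality** is $(k_{in}+k_{out})/(n-1)$.
* **Betweenness** is the fraction of all-pairs shortest directed paths
  through a node, normalized by $(n-1)(n-2)$; **closeness** uses incoming
  distances with per-component scaling, so disconnected webs are handled
  without infinities. Both default to *unweighted* shortest paths even on
  weighted webs: interaction weights are flows, not traversal costs. An
  explicit `weights_as_distance = "inverse"` option uses $1/w$ costs.
* **Trophic level** solves the diet-average linear system
  $s_i = 1 + \sum_j w_{ji} s_j / \sum_j w_{ji}$ with basal species (no
  incoming prey edge) fixed at 1. The solution is unique exactly when
  every consumer is reachable from a basal node; when that precondition
  fails the error names the offending nodes and points at the regularized
  fallback (`fallback = TRUE`), which solves
  $(\mathrm{diag}(u) - A - A^\top) h = k_{in} - k_{out}$ per weak component
  and shifts the minimum to 1. The fallback is never switched on silently.
  Trophic levels depend only on diet *fractions*, so they are invariant to
  uniform weight scaling (tested).
* **Katz centrality** solves $x = \alpha A^\top x + \beta \mathbf{1}$
  directly; defaults $\alpha = 0.1$, $\beta = 1$ (the common toolkit
  defaults). Convergence needs $\alpha < 1/\lambda_{max}$; at or above
  $0.9/\lambda_{max}$ the attenuation is shrunk to that margin with a
  warning, or raises with the computed bound when auto-shrink is off. The
  raw vector is unit-Euclidean-normalized before min–max scaling.
* **Average clustering** uses the all-motif directed triangle definition
  (every orientation counts), $C_i = (S^3)_{ii} / (2(d_i(d_i-1) -
  2d_i^\leftrightarrow))$ with $S = A + A^\top$; self-loops excluded.
* **Hierarchy** is flow hierarchy: the fraction of edges not inside any
  nontrivial strongly connected component (self-loops count as cyclic);
  1 on DAGs, 0 when every edge sits in a cycle, 1 on an edgeless web by
  vacuity. The literature also reads hierarchy through trophic coherence;
  because the two readings are not equivalent we expose that alternative
  behind `method = "coherence"` ($1/(1+q)$, $q$ the trophic-jump
  incoherence on regularized levels) without asserting either reproduces
  any published curve.

## Communities and agreement

Value-based clustering chains sorted values whose successive gaps are at
most `tol` (transitive closure; `tol = 0` groups exact equals) — the
natural way to cluster by trophic level or Katz value. Divisive
Girvan–Newman removes the maximal directed-edge-betweenness edge until the
requested number of *weakly* connected components is first reached;
equal-betweenness ties are broken by the lexicographically smallest
(prey, predator) pair, which makes the dendrogram fully deterministic and
testable. Map-equation (Infomap) detection is exposed only as an adapter
(`detect_communities(web, "infomap")`, delegated to igraph); if the
backend fails the adapter raises a structured "unavailable" error rather
than crashing.

Partition agreement is scored five ways from the contingency table: Rand
index (concordant pair fraction), homogeneity and completeness
(conditional-entropy based, natural logs, $0\log 0 = 0$, score 1 when the
conditioning entropy is 0), V-measure (their harmonic mean) and
Fowlkes–Mallows ($TP/\sqrt{(TP+FP)(TP+FN)}$ over co-membership pairs; two
all-singleton partitions agree perfectly and score 1). All five are
relabeling-invariant and are checked against brute-force pairwise and
entropy oracles on random partition pairs. The expected/reference grouping
for evaluation is always an input file, never inferred.

## Flow tables for Sankey-style comparison

The comparison module is data-first: every figure has a CSV twin.

* `degree_flow` lists each original node's total degree, its group's
  degree sum and mean, and the group node's degree in the simplified web;
  degree totals are conserved into the group column. Group means are
  printed to one decimal in exports, full precision in the CSV.
* `cluster_flux` divides each entity's value by its cluster size (five
  entities at trophic level 2.5 each carry a split of 0.5), assigns the
  standard value 1 to all middle fluxes, and displays each cluster block
  as its outbound unit-flux total floored at 1. The floor matters only for
  singleton clusters with small values; the five-entity cluster shows a
  block of 5 with five outbound links. The printed sources are ambiguous
  about whether blocks carry value sums or link counts; the worked
  five-at-2.5 example is only consistent with unit-flux counting, which is
  what we implement.
* `degree_flow` totals can be read per out-degree or total degree; we use
  total (in + out) degree throughout, since the published group arithmetic
  is consistent with it and the flow caption speaks of node degree.

The Sankey exporter writes a self-contained HTML file embedding the link
table as JSON (recoverable with `read_sankey_html`, tested by round-trip)
plus a minimal SVG rendering; the parallel-coordinates exporter writes SVG
where cairo is available, PDF otherwise. Tests assert on labels, link
counts and the embedded data, never on pixels.

## The synthetic generator

`generate_taxonomy` builds a fully nested lineage tree with deterministic
names and an optional raggedness fraction that blanks fine ranks, matching
how real tables are incomplete. `generate_foodweb` assigns each species a
niche score, designates the `n_basal` lowest-score species as producers,
gives every consumer at least one lower-score prey (so basal reachability
— the trophic precondition — holds for every output by construction) and
adds further lower-score prey links to hit a target connectance. Weights
are i.i.d. integers 1–5 so merged weights are exactly checkable.

This is deliberately *not* the interval niche model of the food-web
literature: we need basal-anchored directed webs with controllable size
and connectance, not ecologically calibrated degree distributions. Raw
generated webs are acyclic; cycles (and self-loops) appear only through
coarsening, which is exactly the regime the simplification tests probe.
Consequently, passing tests demonstrate correctness of the operators and
conventions, not fidelity to the degree or trophic-level distributions of
any empirical web.

Default study conditions used by the tests: 64-species taxonomies (2
taxa per rank below kingdom), 6–10 producers, directed connectance
0.05–0.08, the 6-level default scheme (genus, family, order, class,
phylum). The property suite sweeps 200 generator seeds for the
conservation/monotonicity invariants and 100 random partition pairs for
the agreement oracles; both run comfortably on a single CPU.

## Numerical choices and degenerate inputs

* Linear systems (trophic, Katz) are solved densely with LU; webs of a
  few hundred nodes are far below any performance concern.
* Min–max normalization of a constant vector returns 0s.
* Betweenness is all-zero below three nodes; density is `NA` below two.
* Duplicate edge rows sum rather than error, mirroring the merge
  semantics of lumping and making raw interaction files forgiving.
* Node labels are whitespace-normalized (trim, collapse runs, preserve
  case) before any matching, because taxonomy strings from databases are
  inconsistently spaced.
* Delimiters are sniffed among comma/tab/semicolon and can be forced;
  decimal commas are accepted behind an explicit `dec = ","`.
* All machine outputs use decimal points; every CLI output carries `#`
  provenance comments (version, command, seed) and is written to a
  temporary file renamed on success, so failed runs leave no partial
  output.

* Because self-loops are retained, the density convention $E/(n(n-1))$
  (which counts ordered pairs of *distinct* nodes) can exceed 1 on
  extremely coarsened webs. We keep the convention as is: a density above
  1 is a loud, legitimate signal that lumping has gone too far, and
  rescaling it away would hide exactly what the retention policy is meant
  to expose.

## Known limitations

* The readers expose dialect flags rather than hard-coding any single
  database export format; orientation of interaction matrices is a flag,
  never guessed.
* The map-equation backend is a thin adapter; its internals (and its
  stochastic behaviour across versions) are out of scope.
* Girvan–Newman requires an explicit target community count; the full
  removal history is returned so any other stopping rule can be replayed.
* The coherence-based hierarchy variant is provided for comparison but is
  not claimed to match any published hierarchy trajectory.
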