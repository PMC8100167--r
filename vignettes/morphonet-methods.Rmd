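---
title: "Methods: anatomical network analysis of a metamorphic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical network analysis of a metamorphic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphonet)
```

## The model

`morphonet` treats the external morphology of an arthropod as an undirected,
simple, binary graph: every externally identifiable unit (segment, article,
endite, exite, epipod, flagellum, carapace) is a node, and every physical
contact between two units is an edge.  A developmental series is an ordered
list of such networks, one per phase (here: egg-nauplius, zoea, megalopa,
adult crab).  The package asks how the *organisation* of that graph — its
modularity, hierarchy, complexity, and robustness — changes across
metamorphosis, and classifies each summary statistic as **intensive**
(normalised complexity that falls as the body unfolds) or **extensive**
(manifest, size-like complexity that accumulates).

All analyses operate on a validated `morph_network`: symmetric 0/1
adjacency, zero diagonal, unique labels, connected unless explicitly
allowed otherwise.  Node labels are the identity; input order is preserved
so every downstream tie-break is reproducible.

## Modularity and node roles

Modules are found by multi-level (Louvain) optimisation of Newman–Girvan
modularity

$$Q = \frac{1}{2m}\sum_{ij}\left(a_{ij} - \frac{k_i k_j}{2m}\right)
      \delta(c_i, c_j).$$

Louvain is order-sensitive, so `detect_modules()` runs `restarts` (default
100) passes over seeded random vertex permutations and keeps the best-Q
partition; Q is always recomputed from the formula above by
`modularity_q()`, which is implemented independently of the igraph
routine so the two can cross-check.  On every graph with eight or fewer
nodes the result is verified in the test suite against exhaustive
enumeration of all set partitions.

Node roles use the within-module degree z-score (population standard
deviation; `z = 0` when a module is degree-uniform) and the participation
coefficient $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$.  The seven ZP regions
use the thresholds `P = 0.4` (connector), `P = 0.75` (hyper-connector),
`z = 1` (hub) and `z = 2.75` (super-hub), with all boundaries inclusive on
the high side.

## Topological overlap and hierarchy

The topological overlap of two distinct nodes is
$O_T(i,j) = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with
$l_{ij}$ the number of shared neighbours.  Note that under this (WGCNA)
form two *adjacent* nodes sharing all further neighbours overlap exactly 1,
while two non-adjacent twins reach $k/(k+1)$ — the idealised statement
"identical neighbourhoods give overlap 1" holds exactly only in the
adjacent case, and the unit tests encode the exact values.

Hierarchy trees are average-linkage (the convention of the topological
overlap literature) agglomerations of `1 - O_T`.  "Levels" of a tree are
counted as *distinct merge heights after rounding to 1e-9*; the counting
rule behind published level counts is not stated anywhere, so this
documented rule is a package choice and level counts are treated as soft,
ordinal checks only.

## The complexity battery

All eight measures are normalised to $[0,1]$ and are designed to score
medium-density, heterogeneous graphs high and both minimally connected
(tree) and maximally connected (complete) graphs low.

* **Cr** rescales the adjacency spectral radius between the path
  ($2\cos(\pi/(n+1))$) and complete ($n-1$) extremes and folds through
  $4c(1-c)$.
* **Ce** does the same with global efficiency, rescaled between the path
  graph and the complete graph.
* **MAg** is the product of the mutual information
  $I = \frac1m \sum_{(i,j) \in E} \log\frac{2m}{k_ik_j}$ and the redundancy
  $R = \frac1m\sum_{(i,j) \in E}\log(k_ik_j)$ of the edge-endpoint degree
  distribution.  Because $I + R = \log 2m$ identically, the tempting
  "balance" normalisation $4IR/(I+R)^2$ is degenerate: it awards sparse
  paths values near 1.  The package instead normalises against the
  entropy budget of the complete graph on the same node set,
  $\mathrm{MAg} = 4IR/\log^2(n(n-1))$, which restores the required
  ordering (verified in the tests: path and complete graphs score below a
  medium-density graph of the same size).  The published normalisation is
  not reproducible from the verbal definition; this one is documented and
  trend-faithful.
* **OdC** is the entropy of the offdiagonal sums of the degree–degree edge
  count matrix, over $\log D$ with $D = k_{\max}-k_{\min}+1$ possible
  offdiagonals; regular graphs score exactly 0.
* **ST counts** use the matrix-tree theorem (exact integers to $n = 50$,
  log-domain determinants beyond).  **STS** is the mean relative loss of
  spanning trees over single-edge deletions,
  $1 - \overline{s_e/\mathrm{ST}(g)}$, and **STSD** the normalised spread
  $(\max_e s_e - \min_e s_e)/\mathrm{ST}(g)$.  The published normalising
  denominators for these two are unknown; these variants are the package's
  own, chosen to be exact on the stated anchor cases (edge-transitive
  graphs give STSD = 0, bridges count as total loss).
* **C1e** counts distinct one-edge-deleted subgraphs by spanning-tree count
  and by Laplacian spectrum (eigenvalues rounded to 1e-8 before multiset
  comparison — floating spectra are never bit-equal), divided by $m$.

## Topological descriptors

Nineteen descriptors in four families (distance, other-invariant,
entropy, eigenvalue).  Non-obvious variant choices, all of which have
several published versions:

* *Compactness* is the normalised mean distance $2W/(n(n-1))$ (lower =
  more compact).  A variant rescaled against the path graph was rejected
  because it inverts the published trend direction on sparse growing
  quasi-trees.
* *Centralization* is the unnormalised Freeman degree sum
  $\sum_i (k_{\max} - k_i)$: the published ~175-fold jump between the first
  and third phase is only reachable by an unnormalised variant (a
  centralisation bounded in $[0,1]$ cannot grow 175-fold from a non-trivial
  base), which is how the variant was selected.
* *Vertex orbits* for the information content use iterated neighbourhood
  colour refinement (1-WL), which equals automorphism orbits on trees and
  quasi-trees; the test suite validates refinement against brute-force
  automorphism orbits on small graphs.
* *Bonchev* is the distance-magnitude information index
  $W\log_2 W - \sum_d m_d\, d \log_2 d$; *Bertz* the edge-endpoint degree
  magnitude information $2m\log_2 2m - \sum_i k_i \log_2 k_i$;
  *Balaban-like information* replaces distance sums in J with per-node
  distance-distribution entropies; *edge equality* is the entropy of edge
  classes keyed by unordered endpoint-degree pairs.  All information
  indices use base-2 logarithms.

These variants are validated by trend and closed-form anchors, not by
value-matching any published table.

## Null models

`generate_null()` realises a degree sequence in three stages:
Havel–Hakimi construction (after an Erdős–Gallai check), connectivity
repair by cross-component double-edge swaps (which can never create loops
or multi-edges and strictly merges components), and randomisation by a
seeded Monte-Carlo chain of connectivity-preserving double-edge swaps,
run to `10 * m` accepted swaps by default (a standard mixing heuristic;
the published generator's mixing time is unstated).  A swap is accepted
only if the graph stays simple and connected; connectivity needs a single
targeted reachability test because each fragment of the cut graph contains
one of the four swap endpoints.  `ensemble_compare()` reports
observed/mean ratios over a seeded ensemble; measures that depend only on
$(n, m)$ have ratio exactly 1 by construction.

## Robustness

Global efficiency is the mean inverse shortest-path length over ordered
pairs, with $1/\infty = 0$.  Node vulnerability is the relative efficiency
drop after deleting one node, with the residual efficiency computed over
the remaining $n-1$ nodes (not padded back to $n$; the padded variant
would shift every value by a factor and was rejected as the
non-calibratable option, see limitations).  The rich core ranks nodes by
degree (stable input-order tie-break) and cuts at the first maximum of the
links-to-higher-ranks profile.  Attack curves remove nodes by initial
degree, initial betweenness, recalculated betweenness ("cascading"), or
uniformly at random (averaged over `n_reps = 50` seeded replicates);
connectivity loss after each removal is the severed fraction of ordered
pairs relative to the original count, $1 -
\sum_C |C|(|C|-1) / (n_0(n_0-1))$, which is 0 before any removal and 1
after the last.  Betweenness is undirected, unnormalised, with each
unordered pair counted once and endpoints excluded.

## The synthetic generator and what a green test establishes

`phase_series()` rebuilds the four-phase series from the published anatomy
tables: an axial chain of segments, bilateral appendage chains (mirrored
labels, no cross-links — left and right appendages form separate modules,
as published), a carapace hub linked to head and thoracic segments, and,
for the adult, appendage remodelling followed by `fuse_nodes()` fusions
creating the cephalon, the fused thoracomere 1–4 and the fused
pleomere 3–5.  Chain lengths were fixed once, from the published node and
edge totals per phase (26/29, 77/83, 210/222, 174/178) and plausible
article counts (2–7 per limb); they are not tuned to any downstream
statistic.

The stand-ins therefore reproduce exactly: sizes, degree regime
(mean degree 2.05–2.23, degree-2 dominance), density, and the published
module counts; and they reproduce emergently, without being told to: the
high larval modularity (Q about 0.80 in megalopa and adult), the carapace
as a local super-hub and development-wide betweenness maximum in the
megalopa, the adult betweenness triad with its two role novelties
(connector super-hub cephalon, non-hub hyper-connector fused thoracomere),
the 4-node adult rich core at proportion 0.02, and the adult count of
seven nodes with vulnerability above 0.1.

They do **not** reproduce the unpublished exact wiring, so distance-
and clustering-sensitive published values (average path length, clustering
coefficients, betweenness magnitudes, vulnerability maxima, the large
larval rich cores, the Wiener 144.8-fold ratio) deviate by roughly
5–25%.  A green test on the stand-ins establishes that the *machinery*
reproduces published structure wherever that structure is derivable from
the printed tables — not that the original matrices have been recovered.
The acceptance suite asserts the printed values anyway and leaves the
deviations visible as failures by design.

## Numerical choices

* Spanning-tree determinants: exact integer rounding up to $n = 50$,
  natural-log domain beyond; `-Inf` log-count encodes disconnection.
* Spectra equality for C1e: round to 1e-8 before comparing multisets.
* Merge-height distinctness: round to 1e-9.
* Clustering with degree < 2: both conventions implemented
  (`"exclude"` default, `"zero"` optional).  The intended calibration
  against the published table is impossible without the original matrices;
  `"exclude"` matches the behaviour of the toolchain the analysis emulates.
* Ties everywhere (degree ranks, attack orders, `which.max`) resolve to
  the first index in preserved input order.
* The uniformity smoke test of the null generator uses 600 draws at a
  5-sigma binomial band (scaled down from exhaustive settings to keep the
  default suite fast; the band scales with the draw count).

## Known limitations

* The exact published normalisations of MAg, STS, STSD (and several
  entropy-descriptor variants) are unknown; the package's variants are
  documented above and validated by anchors and trends, so absolute values
  are not comparable to the published ones for these measures.
* Per-step dominance of degree attack over mean random failure does not
  hold universally on quasi-trees (removing a redundantly wired axial hub
  can cost less than an average removal); the attack/error gap is asserted
  on whole-curve areas instead.
* Ensemble comparison with the full measure battery on the largest network
  is the slow path (eigendecompositions per model); use a measure subset
  or a smaller ensemble for interactive work.
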