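---
title: "Methods: phylogenetically adjusted metabolic interaction indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically adjusted metabolic interaction indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomint)
```

## The model

`phylomint` treats each genome-scale metabolic model as a directed graph
over metabolites: every non-boundary reaction contributes an edge from each
substrate to each product, and reversible reactions contribute both
directions. This is the standard reverse-ecology construction — it encodes
*producibility*, not flux: an edge u → v says only that v can be derived
from u by some enzyme in the model.

**Seed sets.** A compound the organism cannot derive from anything else
must come from the environment. On the graph this is exactly membership in
a *source* strongly connected component (SCC): a maximal mutually-reachable
metabolite set with no incoming edge in the SCC condensation. Every member
of a source SCC of size $k$ is interchangeable as the entry point, so each
gets confidence $C = 1/k$; compounds with $C \ge 0.2$ (source SCCs of at
most five metabolites) are retained as the seed set. Seed sets are a proxy
for a nutritional profile, not a growth requirement — they bound what the
organism could in principle need, given its reconstructed network.

**Interaction indices.** For an ordered pair (A, B):

$$\mathrm{MI}_{competition}(A,B) =
  \frac{\sum C_A(\mathrm{Seed}_A \cap \mathrm{Seed}_B)}
       {\sum C_A(\mathrm{Seed}_A)}, \qquad
\mathrm{MI}_{complementarity}(A,B) =
  \frac{|\mathrm{Seed}_A \cap \neg\mathrm{Seed}_B|}
       {|\mathrm{Seed}_A \cap \mathrm{nodes}(B)|}$$

where $\neg\mathrm{Seed}_B$ is B's network nodes minus B's seeds.
Competition is weighted by A's confidences; complementarity deliberately
uses plain cardinalities. Both are asymmetric — (A, B) and (B, A) are
computed independently — and both lie in [0, 1].

**Phylogenetic normalization.** Metabolic similarity tracks relatedness,
so raw indices cannot be compared across pairs at different evolutionary
distances. Pairs are binned by patristic distance (the branch-length sum
between two leaves of a user-supplied tree) into half-open intervals of
width 0.01; bins smaller than the first bin's size are merged into the
closest preceding qualifying bin; each index is Z-scored within its bin
using the sample (n − 1) standard deviation; and values beyond
$|Z| > 2.698$ — the Gaussian equivalent of Tukey's 1.5 × IQR fences — are
flagged as outliers. A directed cooperation edge A → B requires
significantly high complementarity ($Z > 2.698$) *and* low competition
($Z < -1.000$); the competition cut-off is deliberately laxer than the
fence, since requiring two simultaneous full outliers leaves almost no
edges.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `threshold` (seed confidence) | 0.2 | retains source SCCs of ≤ 5 metabolites |
| `width` (distance bin) | 0.01 | branch-length units of the input tree |
| `high`/`low` (outlier fence) | ±2.698 | Z-score; Tukey-equivalent under normality |
| `z_high`, `z_low_competition` (edge rule) | 2.698, −1.000 | strict inequalities |
| `block` (robustness subsampler) | 3 | consecutive CDSs removed per draw |
| `fractions`, `replicates` | 0.70–1.00 by 0.05, 50 | completeness grid of the degradation experiment |

Graph construction switches (`graph_options()`): compartment suffixes are
stripped by default so metabolite namespaces align across models (a
cytosolic and an extracellular copy of a compound collapse to one node);
boundary/exchange reactions and the biomass pseudo-reaction are dropped by
default because they would make every exchanged metabolite an artifactual
source or sink. Both choices are configurable off for single-model
analyses where the original pipeline's behaviour is unknown. No currency
metabolite blacklist is applied by default; `exclude_mets` accepts one.

## Design choices where the procedure was open

- **Eq-3 denominator of zero** (no seed of A occurs anywhere in B's
  network): the index is defined as 0 rather than an error or NaN. It
  keeps the [0, 1] contract and reads as "no measurable interaction"; the
  `shared_namespace` flag in the pair table marks such pairs so users can
  drop them.
- **Zero-variance and singleton bins** yield Z = 0: no outlier is
  detectable from one observation or from constant values.
- **Sample vs population SD** in bin Z-scores: the sample (n − 1)
  estimator is the conventional finite-sample choice; the low-level
  `bin_zscores()` is exposed for anyone who needs the alternative.
- **Bin intervals** are half-open $[kw, (k+1)w)$, so a distance exactly on
  a boundary goes to the upper bin.
- **Forward-merge fallback**: a small bin with no qualifying preceding bin
  merges into the first qualifying later bin. Since the first bin defines
  the minimum size, it always qualifies and the fallback can only trigger
  in degenerate orderings; it exists for totality.
- **Strict inequalities** at every threshold: a value exactly at the fence
  is not an outlier, and an edge requires strictly exceeding both cuts.
- **Seed thresholding is all-or-none per SCC**, since C is constant within
  a component; a tiny tolerance (1e−12) keeps $1/5 \ge 0.2$ true in
  floating point.
- **Infomap is external.** The package guarantees correct link-list export
  (zero-based contiguous ids plus an id-mapping TSV) and tree-output
  parsing; the community-detection optimizer is stochastic and
  version-dependent, so it is not wrapped.
- **Model builders are external** in the robustness module: the
  subsampler and similarity metrics are first-class code, while the
  CDS-to-model reconstruction step is an injectable function (tests use
  synthetic builders; the CLI offers a subprocess hook).

## The synthetic generator

`random_models()` produces reaction sets whose projected graphs contain
*planted* source SCCs: irreversible metabolite cycles that feed outward
into a random reaction soup but receive no incoming edges, so their
members are guaranteed seeds with known confidence $1/k$. This gives every
oracle test a ground truth that is enforced by construction, not by
re-running the method. The generator emulates the structural features the
method consumes — source components, reversibility, shared namespaces —
and nothing else: stoichiometry, compartments, realistic degree
distributions and annotation noise of real reconstructions are absent.
Passing tests therefore demonstrate correctness of the graph-theoretic
machinery, not robustness to reconstruction artifacts in real models.

`toy_networks_fig6()` instantiates the canonical two-network worked
example. Its exact wiring is the minimal graph satisfying the documented
constraints (seed memberships, SCC structure, shared metabolites); the
test suite includes a second, differently wired instantiation of the same
constraints and checks that both give identical indices (1/6 and 1/2), so
the fixture does not over-fit one topology. One caption-level aside: in
network B, metabolites I and J form a two-member SCC, so their confidences
are 1/2 each by $C = 1/|SCC|$; only network A's confidences enter the
worked index values, which are unaffected.

## Numerical and degenerate-input conventions

- Networks are stored with sorted node and edge tables, so equal networks
  are byte-identical and pipeline reruns produce identical TSVs (written
  at 6 significant digits).
- Self-loop edges are dropped at construction: they carry no reachability
  information and would distort source/sink counts.
- An empty focal seed set makes both indices undefined (division by zero)
  and raises a typed error rather than returning NaN.
- The block subsampler draws block start positions uniformly with
  replacement, never wraps around the catalog end (contigs are linear),
  and stops at the first draw where the retained fraction reaches the
  target, which bounds the retained fraction in
  $(\mathrm{target} - \mathrm{block}/n,\ \mathrm{target}]$.
- Patristic distances come from the tree's cophenetic matrix; the tests
  cross-check them against a generic weighted shortest-path computation
  and verify the four-point condition and re-rooting invariance.

## Problem sizes used in the test suite

The suite runs at desk scale: seed-set oracle equivalence on 200 random
digraphs of up to 40 nodes (brute-force transitive closure is quadratic
but trivial there), index contracts on 100 random model pairs, outlier
calibration on 10^5 standard-normal values in a single bin, 1,000
subsampler seeds at 100 CDSs, and pipelines of up to 8 synthetic models.
These sizes make every oracle exhaustively checkable; the pair-enumeration
arithmetic ($n(n-1)$ ordered pairs) is what scales the method to
collections of thousands of genomes, where a full run is embarrassingly
parallel over pairs.

## Known limitations

- Indices inherit every bias of the input reconstructions; incomplete
  genomes inflate seed sets (the degradation module quantifies exactly
  this sensitivity, given a builder).
- Seed sets are producibility arguments, not growth requirements; they can
  over- or under-state true nutritional overlap.
- Metabolite identity across models is string equality after compartment
  stripping — no ontology mapping is attempted, so models must come from a
  shared namespace (e.g. one reconstruction tool).
- The discretized normalization estimates the phylogenetic trend per bin;
  it does not model within-bin trend, and bins far out on the distance
  axis lean on the merge rule for adequate sample size.
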