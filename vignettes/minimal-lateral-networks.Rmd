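---
title: "Detecting hidden lateral transfer with minimal lateral networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hidden lateral transfer with minimal lateral networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mlnet)
```

## The problem

Binary presence/absence characters — cognate sets across languages, gene
families across genomes — mostly descend vertically along a species or
language tree. But both kinds of data also move *sideways*: words are
borrowed between contemporaneous languages, genes transfer horizontally
between lineages. A bifurcating tree cannot represent these events, and
characters acquired laterally masquerade as vertically inherited ones,
producing "patchy" distributions that sit awkwardly on the tree.

`mlnet` infers the minimum amount of lateral transfer needed to reconcile
a set of binary characters with a rooted reference tree, and assembles the
result into a *minimal lateral network* (MLN): the reference tree plus a
set of weighted lateral edges connecting the node pairs (contemporary or
ancestral) that share laterally transferred characters.

## Data model

The package works on two inputs:

* a **reference tree**: rooted, with the contemporary taxa at the leaves
  and hypothetical taxonomic units (HTUs) at the internal nodes. Trees are
  read from Newick; polytomies are resolved deterministically in input
  child order, so a tree over $n$ taxa always has $2n-1$ nodes. Branch
  lengths play no role: inference is purely topological.
* a **presence/absence pattern (PAP) matrix**: characters in rows, taxa in
  columns, entry 1 when the character is attested in the taxon. Long-format
  cognate tables (concept, taxon, cognate class, optional loan flag) are
  converted with `cognate_table_to_pap()`; each (concept, class) pair
  becomes one character. All-zero rows are rejected — an unobserved
  character carries no information. Known-loan flags never change the
  matrix; they are carried as annotations for later validation.

## Bounded-origin parsimony: LO, SO and BOR-k

For a single character with at least one presence, the package infers an
*origin–loss scenario*: an ordered set of origin nodes and a set of loss
nodes such that replaying the origins down the tree, switching presence
off at each loss node, reproduces the observed row exactly. Five
allowances are implemented:

* **LO (loss only)** — the origin is forced to the root; a loss is placed
  at every maximal all-absent clade (a node whose leaves are all absent
  while its parent retains a present descendant). This is the minimum loss
  set given a root origin.
* **SO (single origin)** — the origin moves down to the most recent common
  ancestor (MRCA) of the present leaves; losses as in LO, inside that
  subtree.
* **BOR-k (k = 1, 3, 7, 15)** — up to $k$ additional origins: the first is
  "the" origin, every further one a borrowing. Inference starts from the
  SO origin and repeatedly *splits*: an origin whose subtree still
  contains an absent leaf is replaced by the MRCAs of present leaves
  inside its two child clades. Splitting stops when no origin has absent
  descendants or when the next split would exceed the allowance
  ($k + 1$ origins).

Three conventions in the splitting step were genuinely open and are fixed
as follows:

* **Queue order.** Origins are processed first-in-first-out, i.e. the
  search is level-wise over origins in discovery order. Any order yields a
  valid scenario; FIFO is deterministic and matches the iterated "search,
  then search again in each part" structure of the procedure.
* **Atomic splits.** A split replaces one origin by two (net +1). If only
  the budget for the current number of origins remains, no further split
  occurs — splits are never half-applied.
* **Primary origin.** The first origin finalized in discovery order is
  labelled primary, the rest borrowings. This is a reporting convention
  only: the method infers *that* a borrowing happened, never the donor or
  direction, and no downstream statistic depends on which origin carries
  the label.

Two monotone facts follow from the construction and are enforced as
property tests: along LO → SO → BOR1 → BOR3 → BOR7 → BOR15, per-character
loss counts never increase and origin counts never decrease. Total event
counts (origins + losses) are *not* monotone: a split fires whenever an
origin has an absent descendant, even when the absent clades lie strictly
inside the two child MRCAs, in which case the split adds an origin without
removing a loss. This is inherent to the per-clade-MRCA rule, not an
implementation artifact.

## Ancestral inventories and model selection

Given one scenario per character, the *inventory* of a node is the number
of characters present there after replay. Leaf inventories always equal
the PAP column sums.

An alternative reading would count, per node, only the origins placed
exactly at that node. That quantity is near zero at almost every internal
node regardless of the data, so a distributional comparison against leaf
inventories could never come out non-significant; the presence-based
reading is the one under which the selection criterion below is
meaningful. The origin-count mode remains available via
`ancestral_inventory(..., mode = "origin_count")` for diagnostic use.

Model selection applies a uniformitarian criterion: ancestral inventory
sizes should look like contemporary ones. For each allowance in increasing
order, the internal-node sizes are compared with the leaf sizes by a
two-sided Wilcoxon rank-sum test, and the first model with $p > \alpha$
(default $\alpha = 0.05$) is accepted:

* under LO, every character is ancestral and root inventories equal the
  character count — far too large;
* under SO, loss-generated patchiness still drags origins rootward and
  inflates ancient inventories;
* each extra borrowing allowance moves origins tipward and shrinks
  ancestral inventories; too much allowance overshoots and makes them
  significantly *smaller* than contemporary ones.

The effect size reported alongside $p$ is the fraction of interquartile
range, $(\mathrm{median}_{anc} - \mathrm{median}_{cont}) /
\mathrm{IQR}_{cont}$. Quartiles use linear interpolation (R's default
type 7); the convention matters only for reproducibility. The root counts
as an ancestral node. The Wilcoxon test is computed exactly when the
pooled sample is at most 25 and tie-free, and by the tie-corrected normal
approximation otherwise — at realistic tree sizes (dozens of internal
nodes, heavy ties) only the asymptotic branch is ever exercised, and the
two branches agree within 0.02 at the crossover sizes (property-tested).

When no model attains $p > \alpha$ the selection reports the last model
flagged `none_accepted`. This happens on genuinely intermediate data: at
high borrowing rates BOR1 still leaves ancestral inventories too large
while BOR3 already overshoots below, and the honest answer is that no
allowance reproduces contemporary-like ancestral inventories.

## The minimal lateral network

Every split performed during BOR-k inference produces one *sibling pair*
of origins, and each pair contributes one lateral edge between those two
nodes. Edge weights count contributing characters, so the summed lateral
weight always equals the total number of inferred borrowings — a
conservation law checked on every run. The replaced parent origin carries
no edge: under BOR1 a two-origin character must contribute exactly one
edge between its two origins, and the sibling-pair rule is the recursive
extension of that reading.

Network statistics follow field conventions:

* **connectivity** — distinct lateral neighbours per node, tree branches
  excluded (so the minimum can be 0);
* **clustering coefficient and mean shortest path** — computed on the
  undirected, unweighted union of tree branches and lateral edges over all
  $2n-1$ nodes; local clustering of degree-<2 nodes counts as 0, and path
  lengths average over reachable unordered pairs;
* **edge classification** — external–external, external–internal,
  internal–internal by endpoint kind; lateral edges at external nodes
  represent comparatively recent transfers, and
  `recent_borrowing_fraction()` expresses the characters on them as a
  percentage of each leaf's inventory;
* **group analysis** — with a taxon-to-group map (e.g. main branches of a
  family), an internal node belongs to a group only when all its
  descendant leaves do; mixed nodes belong to none and their edges count
  as external for the groups they touch. Frequencies are normalized per
  node inside (internal edges) and outside (external edges) the group, and
  internal vs external edge weights are compared with a one-sided
  two-sample Kolmogorov–Smirnov test (H0: internal ≤ external,
  asymptotic p — edge weights are heavily tied, so no exact p exists).

For validating against known borrowings, a (character, taxon) item is
*detected* when the character's scenario has at least two origins, and is
classified by the origin containing the taxon: `external` when the taxon
is itself an origin node, `internal` when it descends from an internal
origin. The primary/borrowing labelling plays no role here — it is a
discovery-order convention, and a known borrowing lands on the
first-discovered side about half the time.

## Shared-character network and communities

`shared_matrix()` builds the weighted taxa-by-taxa network whose entries
count jointly present characters (diagonal: inventory sizes).
Because this network is complete or nearly so on real data — a single
ubiquitous character already links every pair — community structure is
only visible through the weights, and the package therefore uses the
weighted generalization of modularity throughout:
$Q = \sum_c \left[ W_c/W - (S_c/2W)^2 \right]$ with weighted degrees,
diagonal excluded.

`leading_eigenvector_communities()` maximizes $Q$ by recursive spectral
bisection on the generalized modularity matrix. Numerical conventions: a
dense symmetric eigensolver (networks here have at most a few hundred
nodes, so determinism is worth more than sparsity), eigenvector entries
equal to zero assigned to the positive side, a group declared indivisible
when its leading eigenvalue or the modularity gain of its best split is
below $10^{-10}$, and disconnected components handled separately. No
Kernighan–Lin refinement sweep is applied; the spectral step alone defines
the procedure here, and a refinement pass is left as future work.

## The simulator

`simulate_pap()` generates data under the process the inference assumes:
each character originates at one node, is inherited down the tree with an
independent per-branch loss probability $q$, and receives a Poisson
number of borrowing events, each copying the character to a uniformly
chosen node not currently carrying it, from which it again propagates
down with loss $q$. Recipients may be internal (ancient transfers,
yielding internal–internal lateral edges) or leaves (recent transfers).
Characters that end up absent from every leaf are redrawn. A single seed
governs all draws, and the full event log is returned as ground truth.

Origins are drawn uniformly over the *internal* nodes. This is a
deliberate choice: characters are innovations of ancestral lineages, and
restricting origins to ancestral nodes is what makes the emitted data
uniformitarian at $\lambda = 0$ — ancestral and contemporary inventories
are then exchangeable, so the selection criterion has a true null to
recover. Drawing origins over all nodes instead (available as
`origin_pool = "all"`) floods the leaves with leaf-private characters,
systematically inflates contemporary inventories, and no allowance can
reconcile the two distributions; that mode is kept for studying exactly
this failure.

Defaults are the package's reference study conditions: 500 characters,
$q = 0.05$ per branch, $\lambda = 0.6$ borrowings per character, on
32-leaf random trees (`ape::rtree` topologies). With them:

* at $\lambda = 0$ a single-origin model (SO, or LO when losses vanish)
  is accepted;
* at $\lambda = 0.6$ BOR1 is accepted, and the inferred borrowing rate
  (≈0.5–0.6 per character) approaches the true rate from below;
* at $\lambda = 2$ no allowance fits — BOR1 remains significantly high,
  BOR3 significantly low — and the best-supported model shifts to
  allowance ≥ 4;
* randomizing the leaf labels of the reference tree destroys the vertical
  signal and pushes the selected allowance strictly higher.

These recoveries, the >80% detection of cross-clade reinserted
borrowings, and the event-count lower bound under the accepted model are
recomputed by the test suite (20 seeded replicates per condition) and by
`scripts/acceptance.R`.

What the simulator does **not** emulate: rate heterogeneity across
characters or branches, donor–recipient geography (recipients are chosen
uniformly, real borrowing is contact-structured), correlated borrowing of
multiple characters in one contact event, semantic shift or
re-classification noise in cognate judgements, and branch-length-dependent
loss. Passing the recovery experiments therefore shows the inference is
correct *under its own model assumptions*, not that those assumptions
hold for any particular empirical dataset.

## Inference is a lower bound

Parsimony counts the minimum number of borrowings needed to explain the
data under the accepted allowance. Under that model the inferred mean
borrowing rate is a lower bound on the simulated truth and increases
monotonically with the true rate. Under larger allowances than the data
support, the bound property fails in the other direction: BOR15 happily
splits patchiness that was actually created by loss, over-reporting
borrowings — one more reason the allowance must be chosen by the
inventory criterion rather than taken as large as possible.

## Worked example

```{r example}
tree <- read_newick(system.file("extdata", "toy_tree.nwk", package = "mlnet"))
cognates <- read_cognate_table(
  system.file("extdata", "toy_cognates.tsv", package = "mlnet")
)
pap <- cognate_table_to_pap(cognates)
pap_summary(pap)

sc <- infer_scenarios(tree, pap, "BOR1")
tidy(sc)

net <- build_mln(tree, sc)
tidy(net)
classify_edges(net)
```

```{r simulated, fig.width = 6, fig.height = 4}
tr <- random_reference_tree(24, seed = 1)
sim <- simulate_pap(tr, n_characters = 300, q = 0.05, lambda = 0.6, seed = 2)
sel <- select_model(tr, sim$pap)
tidy(sel)
autoplot(sel)
```

## Known limitations

* Donor and direction of transfer are not inferred; lateral edges are
  undirected and the primary-origin label is a convention.
* Branch lengths are ignored; a long and a short branch are equally
  likely to lose a character.
* The borrowing count per character is a parsimony minimum under the
  accepted allowance; true rates can only be higher.
* The selection criterion compares whole distributions; it has no power
  to localize *which* internal nodes are mis-sized.
* On data whose true borrowing rate sits between two allowances, no model
  may be accepted; the package reports this state explicitly rather than
  forcing a choice.
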