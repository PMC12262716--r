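---
title: "Consensus and entropy diagnostics for spatially aware clustering"
author: "spacon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus and entropy diagnostics for spatially aware clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacon)
```

# The problem

Spatially aware clustering (SAC) methods partition spatial omics
observations — Visium spots, Visium HD bins, or segmented cells — into
spatial domains using expression and location jointly. Different
methods, and different configurations of the same method, routinely
produce different domain maps of the same tissue, and expert "ground
truth" annotations are themselves one more labeling with their own
granularity and biases. Rather than crowning a single winner against a
possibly unreliable reference, `spacon` treats the set of labelings as
the object of study: it quantifies where methods agree and disagree,
selects a coherent subset of base clusterings, and synthesizes them
into a consensus labeling whose construction is fully auditable.

Everything operates on a deliberately minimal data contract — one TSV
of `obs_id → label` per clustering, one TSV of `obs_id → x, y`, an
optional JSON of provenance — so any upstream method can feed it. The
central container, `LabelingCollection`, extends
`SummarizedExperiment`: the `labels` assay is the N × M matrix of
per-column dense label codes, `rowData` carries the shared coordinates,
and `colData` the per-column provenance.

# Entropy metrics

Both diagnostics reduce to the Shannon entropy of a categorical vector,
$H(X) = -\sum_i p_i \log p_i$ with empirical class frequencies $p_i$.
All entropies are in **nats** (natural log): the convention is fixed
once here so that the bound for an m-class neighborhood is $\log m$.

**Smoothness entropy (SE).** For every observation, the entropy of the
labels of the observation itself plus its k nearest spatial neighbors;
the scalar SE of a labeling is the mean over observations. A labeling
that paints contiguous domains has SE near 0; salt-and-pepper labelings
score high. The default neighborhood is k = 6, matching the typical
coordination number of spot arrays; SE applies no distance cutoff by
default (a cutoff is available via `buildKnnGraph(maxDistance =)`).
Observations whose neighbor list becomes empty after distance filtering
contribute entropy 0 — an isolated observation cannot be unsmooth.

**Cross-method entropy (CME).** Labels from different methods are
arbitrary codes, so columns are first aligned by solving the assignment
problem on the confusion matrix (Hungarian method, `clue::solve_LSAP`);
when a column has more classes than the reference, the confusion matrix
is padded with zero-overlap dummy classes and surplus classes get fresh
codes beyond the reference alphabet, in ascending order of their
original code. Because the choice of reference is arbitrary, the
per-observation entropy across aligned labels is computed once for
every reference column and averaged. CME is reported unnormalized;
`normalized = TRUE` divides by the log of the largest aligned alphabet.
The reference is never aligned to itself (the map would be the
identity), which is why reference averaging is exactly order-free.

**k-NN construction.** Exact Euclidean search; equidistant ties break
by ascending observation id, so graphs are reproducible across runs and
platforms. This matters on lattices, where ties are the rule: on a
unit-spaced chain `A A B B` with k = 1, the third spot's tie resolves
to its left (A-labeled) neighbor, so border detection at k = 1 sees one
border spot, not two. Border detection defaults (k = 4, distance cutoff
1.5) give rook-plus-diagonal adjacency on unit lattices.

**Agreement.** Pairwise ARI uses the permutation-model adjusted Rand
index from the contingency table. In the degenerate case where the
expected index equals the maximum (for instance two single-class
columns) the score is defined as 1 if the two vectors induce the same
set partition and 0 otherwise. NMI uses arithmetic-mean normalization
$2I/(H_1 + H_2)$.

# Base-clustering selection

Selection is context-dependent and auditable: every rule returns a
`SelectionReport` listing survivors and removals with reasons.

* `filterImbalanced()` removes columns whose modal class *strictly*
  exceeds a threshold (default 0.9) — a clustering with >90% of
  observations in one cluster carries little structure. Exactly 90% is
  kept.
* `selectSmoothest()` ranks by SE (ascending), optionally keeping only
  the smoothest column per method first so that no single algorithm
  dominates the consensus, then cuts to the n best. Ties break by
  lexicographic provenance so reruns are stable.
* `concordanceBlock()` hierarchically clusters the rows of the pairwise
  ARI matrix (Euclidean distance on full rows including the diagonal,
  complete linkage), cuts the tree into `nGroups` (default 2), and
  keeps the group with the highest mean within-group ARI among groups
  of at least `minBlockSize` members (default 3 — a consensus of fewer
  than 3 labelings is degenerate). The mean-internal-ARI criterion
  makes the visual "pick the concordant block" step reproducible when a
  cut yields more than two groups.

# Consensus algorithms

**K-modes** treats the N × M label matrix as categorical data and
minimizes the total Hamming distance of rows to cluster-specific mode
vectors. Initialization samples K distinct rows; mode ties resolve to
the smallest code; an emptied cluster is re-seeded from the row
farthest from its current mode. The objective is non-increasing within
a run and the best of `nStarts` (default 10) restarts is returned.

**LCA** fits the categorical mixture
$P(x_i) = \sum_k \pi_k \prod_m \theta_{mk,x_{im}}$ by EM: an unobserved
latent class (the consensus cluster) generates the observed labels,
conditionally independent across methods. Disagreement is absorbed by
the method-specific conditionals rather than distances. The
$\theta$-updates add a Dirichlet pseudocount (default 0.1), i.e. MAP
estimation; the trace reported in `objectiveTrace()` is therefore the
**penalized** log-likelihood, which EM provably never decreases — the
observed-data log-likelihood alone is not guaranteed monotone under MAP
updates and is stored separately in the fitted `LcaModel`. With a
single base clustering the mixture is non-identifiable (collapsed and
separating solutions have equal likelihood, and the smoothing prior
favors the collapse), so `lcaConsensus()` special-cases M = 1 with K
equal to the column's alphabet: it returns the EM fixed point seeded at
the column itself, making a lone base clustering its own consensus.

**Weighted JSD consensus** minimizes
$\sum_m \omega_m\,\mathrm{JSD}(S\|S^{(m)}) + \lambda \sum_m \omega_m \log \omega_m$
over a consensus co-association matrix $S \in [0,1]^{N \times N}$ and
simplex weights $\omega$, where $S^{(m)}$ is the binary co-association
matrix of column m and the divergence is the entrywise Bernoulli
Jensen–Shannon divergence summed over distinct pairs (unit diagonals
are excluded — self-pairs carry no information). The entropy term keeps
the weights from collapsing onto one base clustering. Optimization
alternates two exactly solvable sub-problems: for fixed $\omega$ each
entry $s_{ij}$ solves a 1-D convex problem that depends only on the
weighted vote $\sum_m \omega_m s^{(m)}_{ij}$ (solved once per distinct
vote value); for fixed S the Lagrangian gives
$\omega_m \propto \exp(-\mathrm{JSD}(S\|S^{(m)})/\lambda)$. Each step
is an exact minimizer, so the objective is non-increasing; on small
instances the alternating solution matches a black-box optimizer of the
full objective to 1e-4. S is initialized at the unweighted
co-association average and $\omega$ at uniform.

A practical note on $\lambda$ (default 0.1): the divergences are
*sums* over the $N(N-1)/2$ pairs, so their differences grow
quadratically with N while $\lambda$ does not. At realistic sizes the
softmax is then effectively winner-take-all and the method returns the
divergence-medoid base clustering — already a sensible, interpretable
consensus — while large $\lambda$ (on the order of the pair count)
recovers uniform weighting and genuine averaging. Users who want
intermediate regimes should scale $\lambda$ with
$N(N-1)/2$.

The converged S is thresholded (entries below `sparsify = 0.01`
dropped) into a weighted graph and partitioned with the Leiden
algorithm (modularity objective, igraph). When a target cluster count K
is requested, `resolutionSearch()` bisects the resolution parameter
under the assumption that the cluster count is non-decreasing in
resolution, doubling the upper bound (and halving the lower) up to
three times if the target lies outside the bracket, and falling back to
the nearest achieved count (ties favor fewer clusters) with a warning.
Dense N × N storage caps the method at 20 000 observations by default;
larger inputs are rejected with an explicit error rather than silently
thrashing.

All three algorithms are label-permutation equivariant, deterministic
given their seed, and return a `ConsensusResult` carrying labels, the
objective trace, convergence flag and (for the weighted method) the
per-column weights.

# Validation without ground truth

`leaveOneOut()` scores every base clustering against a consensus of its
peers: for each column, the `nBase` (default 6) smoothest remaining
columns — deduplicated per algorithm — form a pseudo-ground-truth
consensus, and the column's ARI against it is reported. Outlier
labelings score near 0 while members of the consensus core score near
1, without ever consulting an external annotation.

`sweepGrid()` maps the mean CME over a grid of (number of clusters k ×
number of smoothest methods n). Granularities at which independent
methods agree after alignment show low mean CME, so the arg-min over k
is a data-driven granularity suggestion. Cells with fewer than n
available columns are marked infeasible rather than erroring, keeping
grids rectangular; n = 1 cells are 0 by definition (one labeling cannot
disagree with itself) and carry a `degenerate` flag so they are not
mistaken for evidence. These outputs are guidance for an
expert-in-the-loop workflow, not a standalone performance metric.

# The synthetic tissue generator

`generateTissue()` places observations on a square lattice with unit
spacing; domains are horizontal bands of near-equal height ("layers",
emulating laminar cortex) or a rectangular tiling ("blocks"). Every
domain is connected on the 4-neighbor lattice and non-empty.
`perturbLabeling()` then emulates the failure modes of real SAC
outputs, applied in a fixed order: domain merges and splits
(granularity mismatch), boundary jitter — observations within a
lattice-step radius of a domain border are reassigned to the nearest
foreign domain with a given probability (boundary disagreement) —
independent label flips (salt-and-pepper noise), and finally a random
permutation of the label codes (methods name clusters arbitrarily).
Generators are pure functions of their seeds and restore the caller's
RNG state.

What the generator does *not* emulate: gene-expression measurements and
their noise structure (only label outputs are simulated), hexagonal
spot geometries, spatially correlated error fields beyond the boundary
band, and systematic method biases such as shared preprocessing.
Passing tests on these fixtures therefore demonstrate the correctness
and calibration of the metrics and algorithms on labelings with known
truth — not that any particular SAC method is good, nor that consensus
will rescue pathological real data.

Default noise conditions used across tests and the acceptance run —
10% label flips, boundary jitter within 1 lattice step at probability
0.3, label permutation on — correspond to base clusterings that agree
with the truth at ARI roughly 0.6–0.7, the regime where consensus is
useful but not trivial. Problem sizes are kept deliberately moderate
(lattices of 120–1200 observations, M of 3–8, the categorical-mixture
recovery at N = 500) so the full suite runs in a couple of minutes;
all the algorithms scale to the tens of thousands of observations
typical of real sections, with the weighted method's quadratic memory
as the stated exception.

# Numerical choices and edge cases

* Natural log everywhere; `0 log 0 = 0` by convention.
* Collections take the **intersection** of observation ids (consensus
  needs a complete matrix); dropped ids are recorded. Coordinates must
  agree across labelings within 1e-6 per axis.
* Observation order is C-collation lexicographic, independent of
  locale.
* k-NN ties: ascending observation id. K-modes assignment ties: lowest
  cluster index; mode ties: smallest label code.
* ARI degenerate case (expected = maximum index): 1 iff identical set
  partitions, else 0.
* LCA class priors are clamped at 1e-12 before normalization to keep
  the E-step finite when a class empties.
* Consensus labels are re-coded by order of first appearance, so equal
  seeds give bit-identical outputs.

# A worked run

```{r example, eval = FALSE}
tissue <- generateTissue("layers", 20, 15, 4, seed = 1)
specs <- lapply(1:6, function(m)
  noiseSpec(flipRate = 0.1, permuteLabels = TRUE, seed = m))
sim <- generateCollection(tissue, specs)

se <- smoothnessScores(sim$collection)
cme <- crossMethodEntropy(sim$collection)
fit <- lcaConsensus(sim$collection, K = 4, seed = 1)
ariScore(consensusLabels(fit$result), labelCodes(sim$gt))
```

The same workflow is scriptable from a shell via the thin CLI wrapper
(`system.file("scripts", "spacon", package = "spacon")`), whose
subcommands `simulate`, `metrics`, `select`, `consensus`, `cme`,
`loo`, `sweep` and `convert` read and write the TSV/JSON dialect and
drop a resolved-config JSON next to every run's outputs.

# Known limitations

* The weighted method's dense co-association matrices are quadratic in
  N; use K-modes or LCA beyond ~20 000 observations.
* Consensus uses no spatial information of its own — spatial coherence
  enters only through SE-based selection of the inputs.
* The CME reference-averaging loop is O(M²) alignments; at very large M
  consider subsetting to a concordance block first.
* Majority voting and linkage-ensemble consensus are deliberate
  non-goals; the three implemented algorithms span distance-based,
  model-based and similarity-based designs.
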