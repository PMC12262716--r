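# spacon — consensus clustering and entropy diagnostics for spatial domain detection

Spatially aware clustering (SAC) methods partition spatial omics
observations (spots, bins, cells with x–y coordinates) into tissue
domains. Run several methods — or several configurations of one — on
the same section and you get several different domain maps, with no
trustworthy external annotation to arbitrate: expert "ground truth"
labels are one more labeling with their own granularity and biases.

`spacon` is for analysts holding such a pile of labelings. It

* measures spatial coherence per labeling (**smoothness entropy**, SE)
  and localized inter-method disagreement (**cross-method entropy**,
  CME, with Hungarian label alignment),
* builds pairwise agreement matrices (ARI/NMI) and applies auditable
  selection rules (class-imbalance filter, smoothest-per-algorithm
  ranking, concordance-block detection on the ARI tree),
* synthesizes a consensus labeling by three algorithms — **K-modes**,
  **latent class analysis** (EM on a categorical mixture), and a
  **weighted Jensen–Shannon-divergence co-association consensus**
  partitioned with Leiden,
* validates without ground truth (**leave-one-out** pseudo-GT ARIs) and
  suggests a cluster count via a **mean-CME sweep** over
  (clusters × methods) grids,
* ships a **synthetic lattice-tissue generator** (layered/block domains;
  flip noise, boundary jitter, merges/splits, label permutation) so the
  whole pipeline is testable with known truth.

## The core quantities

For a label vector with class frequencies $p_i$, the Shannon entropy is
$H(X) = -\sum_i p_i \log p_i$ (natural log, nats). SE is the mean over
observations of the entropy of {own label} ∪ {labels of the k = 6
nearest neighbors}; CME is the per-observation entropy across M
base-clustering labels after aligning each column to a reference by
maximum-overlap assignment, averaged over all M reference choices.

The weighted consensus solves

$$\min_{S,\,\omega}\ \sum_{m=1}^{M} \omega_m\, \mathrm{JSD}\!\left(S \,\|\, S^{(m)}\right) + \lambda \sum_{m=1}^{M} \omega_m \log \omega_m, \qquad \sum_m \omega_m = 1,\ \omega_m \ge 0,$$

where $S^{(m)}$ is the binary co-association matrix of base clustering
m ($s^{(m)}_{ij} = 1$ iff i and j share a label), JSD is the entrywise
Bernoulli Jensen–Shannon divergence summed over distinct pairs, and the
entropy term regularizes the weights. Alternating exact updates
(per-entry 1-D convex minimization for S; softmax
$\omega_m \propto e^{-D_m/\lambda}$ for the weights) drive the
objective monotonically down; Leiden community detection on S, with a
binary search over the resolution parameter, yields the final clusters.

## A worked example

```r
library(spacon)

tissue <- generateTissue("layers", 20, 15, 4, seed = 1)   # 300 obs, 4 bands
specs  <- lapply(1:6, function(m)
  noiseSpec(flipRate = 0.1, permuteLabels = TRUE, seed = m))
sim    <- generateCollection(tissue, specs)
sim$collection
#> LabelingCollection: 300 observations x 6 base clusterings
#>   cluster counts: 4, 4, 4, 4, 4, 4

round(unname(smoothnessScores(sim$collection)), 3)
#> [1] 0.325 0.417 0.382 0.411 0.389 0.408
meanEntropy(crossMethodEntropy(sim$collection))
#> [1] 0.2366
```

Six labelings of one tissue, each a 10%-flipped, label-permuted copy of
the truth: SE around 0.3–0.4 nats says each map is fairly smooth but
noisy; mean CME 0.24 nats says the methods disagree at a minority of
observations (the flip sites) once labels are aligned.

```r
fit <- lcaConsensus(sim$collection, K = 4, seed = 1)
fit$result
#> ConsensusResult (lca): 300 observations, 4 clusters
ariScore(consensusLabels(fit$result), labelCodes(sim$gt))
#> [1] 0.9911
max(apply(labelMatrix(sim$collection), 2, ariScore, b = labelCodes(sim$gt)))
#> [1] 0.8387
```

The LCA consensus (ARI 0.99 against the generating truth) is
substantially better than the best single input (0.84) — the point of
consensus clustering in one pair of numbers.

A thin command-line wrapper covers the same workflow from a shell
(`simulate`, `metrics`, `select`, `consensus`, `cme`, `loo`, `sweep`,
`convert` subcommands over the TSV/JSON dialect):

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "spacon", package = "spacon"))')
$CLI simulate --rows 20 --cols 15 --domains 4 --m 6 --flip-rate 0.1 --seed 1 --out-dir run/
$CLI consensus --labels run/labels_method01.tsv,run/labels_method02.tsv,... \
               --coords run/coords.tsv --algorithm lca --k 4 --out-dir run/
```

Every run writes a resolved-config JSON next to its outputs; identical
configs and seeds reproduce outputs byte for byte.

## Documentation

The methods vignette (`vignettes/consensus-workflow.Rmd`) describes the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and the package's numerical conventions and edge-case decisions.
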