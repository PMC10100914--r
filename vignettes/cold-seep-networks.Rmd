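---
title: "Cross-domain co-occurrence networks for cold seep sediment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain co-occurrence networks for cold seep sediment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seepnet)
```

## The scientific problem

Cold seep sediments host bacteria, archaea and fungi whose joint dynamics are
observed only through marker-gene counts: 16S rRNA amplicons for prokaryotes
and 18S amplicons for fungi. Three questions drive this package:

1. Which taxa co-occur, conditionally on all others, across sediment samples —
   i.e. what does the cross-domain interaction network look like?
2. How does the presence of one domain (notably fungi) change the network's
   robustness to random loss of taxa and its capacity to move information
   (metabolites, signals) between members?
3. Which fungal taxa track the methane gradient that peaks in the
   sulfate–methane transition zone (SMTZ)?

Each question gets a module: sparse network inference on
centered-log-ratio (CLR) data, random-attack robustness plus nodal
efficiency, and cross-validated balance selection against a discretized
methane response. A synthetic-community generator with known ground truth
supplies the data for every validation in this package.

## Preprocessing model

Marker-gene counts are compositional: only relative information survives
sequencing. We therefore:

- **Filter** taxa to those present in at least 30% of samples *and* with mean
  relative abundance at least `1e-4`. "Mean across samples" is our reading of
  the abundance rule (the stricter and more common one); a `max` variant is
  available via `abundance_stat`. Filtering is idempotent.
- **CLR-transform** within each marker block separately:
  `x -> ln(x + 1) - mean(ln(x + 1))` per sample, 16S taxa and 18S taxa each
  closing to their own sequencing library. Pseudocount 1 on counts is the
  default of the penalized-inference tooling this mirrors; it is
  configurable. Every sample row sums to zero within a block — an identity
  the tests assert.
- **Discretize methane** into `high`/`low`. Default rule: a sample is `high`
  iff its depth interval overlaps the SMTZ, taken as 10–13 cm below sea
  floor (an alternative reading of the transition zone as 10–12 cm exists;
  the interval is a parameter). A concentration-based rule (`high` iff
  methane exceeds the site's surface-layer mean) is provided for data with
  reliable porewater chemistry.

## Network inference

The estimator is penalized neighborhood selection: each taxon's CLR profile
is lasso-regressed on all others along a log-spaced path of `nlambda = 20`
penalties from `lambda_max` (the largest absolute off-diagonal correlation)
down to `lambda_max * 0.005`. An edge is selected at a penalty if either of
its two directed coefficients is nonzero.

**Penalty selection (StARS).** On each of 20 subsamples (size
`min(floor(10*sqrt(n)), floor(0.8*n))`, without replacement) the full path is
refitted; an edge's selection frequency `f` yields the instability
`2 f (1 - f)`, averaged over all node pairs. The instability is monotonized
from the sparse end (running maximum along decreasing penalty) and the
smallest penalty whose monotonized instability stays at or below 0.05 is
selected: the densest graph that is still stable under subsampling.

**Latent-variable adjustment.** Sequencing depth and environmental gradients
act as dense latent factors. For each candidate rank `r` up to
`latent_rank_max`, the top `r` principal components are removed from the
column-centered CLR matrix and the refit is scored by an extended BIC over
the penalty path. The eBIC charges for the selected edges *and* `p * r`
factor loadings (`r * p * log(n)`), so removing components must buy a real
likelihood gain; without that term the selector always chooses the maximum
rank, even on independent data. The adjustment is off by default
(`latent_rank_max = 0`) and its chosen rank is recorded in network
provenance when engaged.

**Finalization.** The model is refitted on the full data at the selected
penalty; the two directed coefficients of each pair are symmetrized by
keeping the larger magnitude (ties go to the regression whose response node
sorts first), the kept coefficient's sign and size become the signed edge
weight, and isolated nodes are dropped (the input and connected counts are
both recorded). Edge weights are refit lasso coefficients used like
pseudocorrelations — only their signs and relative magnitudes are consumed
downstream.

The five domain variants (BAF, BA, BF, B, F) are tuned and fitted
independently on their own taxon subsets, each re-CLR-transformed after
subsetting.

### What the null and recovery experiments show — and do not show

On synthetic communities from a known sparse precision matrix (40 taxa, 5%
edge density, 400 samples) the full chain — counts, filtering, CLR,
inference — recovers edges at median precision above 0.6 and recall above
0.4 over ten replicate worlds, and on independent taxa (identity precision,
single marker block) it selects essentially no edges.

Two caveats are deliberate findings of the validation work, not footnotes:

- **Small CLR blocks carry closure cliques.** With only 4 taxa in a marker
  block, the per-block zero-sum constraint forces pairwise correlations near
  `-1/3` among them; those negative edges are *stably* selected even when
  the generating precision is the identity. This is a property of
  compositional closure, not a false positive of the estimator (iid
  Gaussian input yields zero edges). Interpret dense negative subgraphs
  inside very small marker blocks (e.g. a fungal-only network with a
  handful of taxa) accordingly. The null-recovery experiment uses a
  single-marker community for exactly this reason.
- **A dominance-structured community concentrates closure.** When a few taxa
  hold large compositional shares, closure correlation concentrates into
  their pairs instead of spreading thinly; some such edges can pass
  stability selection. Tools built on CLR share this behaviour.

## Random-attack robustness and vulnerability

Each attack iteration removes the `N` nodes in a uniformly random order,
tracking `sigma(i)`, the size of the largest connected component after `i`
removals relative to the initial `N` (with `sigma(N) = 0` — the formula sums
to `i = N` and this convention makes the complete-graph value exact).
Robustness is the area under the curve, `R = (1/N) sum_i sigma(i)`, and
vulnerability `V = 0.5 - R`. Closed forms anchor the implementation:
`V(K_N) = 1/(2N)` (so 0.05 for `K_10`), `V` of an edgeless 10-node graph is
exactly 0.41, and the 10-node star has expected `V = 0.17` by enumeration
over the hub's position in the removal order. For any simple graph,
`1/(2N) <= V <= 0.5 - (N-1)/N^2`.

Internally, each iteration is processed in reverse as node *additions*
tracked by a union–find structure, making an iteration near-linear in nodes
plus edges; 10,000 iterations on study-sized networks take seconds. One
master seed derives one sub-seed per iteration (a multiplicative mix, so
streams of nearby seeds do not collide).

Vulnerability distributions of two networks are compared with Welch's
unequal-variance t-test on the per-iteration samples, plus the percent
change in mean V. At 10,000 iterations any real difference has an
astronomically small p-value; the report says so and the effect size is the
number to read. Degenerate zero-variance pairs (e.g. complete vs edgeless)
get `p = 1` when means are equal and `p = 0` otherwise, with a flag.

**Nodal efficiency** is `E(i) = (1/(N-1)) sum_{j != i} 1/d(i, j)` on the
unweighted topology, with unreachable pairs contributing 0; complete-graph
nodes score 1 and isolated nodes 0. Efficiencies are compared across
networks with Welch's t-test on the per-node values.

Signed weights never enter shortest paths: there is no canonical mapping
from a co-occurrence strength to a distance, so betweenness, components and
efficiency are topological, and weights appear only as `|weight|` summaries.

## Keystones, core, and domain contrasts

Degree and betweenness (unweighted, standard multiplicity normalization,
unnormalized by size) are computed per node, plus the mean absolute incident
edge weight. Keystone taxa are those at or above the 80th-percentile
(linear-interpolation quantile) of *both* degree and betweenness; ties at
the threshold are included, so an all-tied network makes every node a
keystone — the degenerate case is documented rather than special-cased. The
core network keeps nodes in the top half of both metrics, takes the induced
subgraph, drops nodes with fewer than 3 edges in it, then drops isolates —
in that fixed order, since the two filters do not commute.

Domain contrasts (e.g. fungal vs bacterial edge weights) use the two-sample
rank-sum (Mann–Whitney) test. A signed-rank test requires paired
observations, which independent domain groups do not provide; the report
names the test it ran. Each domain's share of the pooled top-20% tail of the
metric is reported alongside, with the pooling done across the whole table.

## Balance selection against the methane response

A balance over disjoint taxon groups of sizes `p` and `q` is
`B = sqrt(pq/(p+q)) (mean log x_num - mean log x_den)` on zero-replaced
counts (pseudocount 1; a Bayesian-multiplicative replacement is *not*
reimplemented). `B` is antisymmetric under swapping groups and invariant to
per-sample scaling — both tested properties.

The screen runs repeated stratified 5-fold cross-validation. In each
training portion, all taxon pairs are scored by the AUC of their balance as
a threshold-free ranking classifier; the best pair seeds a greedy search
that adds one taxon to either side while the training AUC improves, up to 8
taxa. Key numerical choices:

- **Stopping (`min_improve = 0.02`).** The empirical AUC at ~160 training
  samples has a standard error near 0.04 and is quantized in steps of
  `1/(n_high * n_low)`; accepting gains below about half that standard error
  lets *persistent* chance correlates of the response ride into every fold's
  balance and cross the 30% screen. A floor of one AUC point (0.01) was
  measurably insufficient; 0.02 removes the stowaways without affecting
  genuine signal recovery.
- **Orientation.** The side elevated in `high` training samples is
  determined by the sign of the mean balance difference; taxa ending on that
  side count toward the "high-favoring" frequency that the signature screen
  thresholds (default 0.30). Overall appearance (either side) is reported
  too.
- **Scale.** 100 repeats x 5 folds = 500 validation steps by default — a
  desk-scale stand-in for the 2,000-repeat (10,000-step) production screen;
  `n_repeats` is a parameter.
- **Null calibration is an ensemble.** Under a *single* fixed label
  permutation, some taxon genuinely correlates with those labels in-sample
  and recurs in most folds — at any stopping rule. The meaningful null
  draws a fresh permutation per repeat; under that ensemble the maximum
  appearance frequency stays well under the 30% screen.

The planted-signal experiments (two-taxon signal, effect size 2, 200
samples, 30 taxa) use unit-scale latent noise so that the planted
log-ratio shift of 2 corresponds to a per-pair AUC above 0.9; both planted
taxa are recovered in every validation step and no decoy reaches 30%.

## The synthetic-community generator

The generator is first-class, tested code; every claim above is validated
against it.

- **Dependence structure** (`make_true_model`): sparse symmetric support at
  the requested density, magnitudes uniform on [0.3, 0.6] with random signs,
  diagonal inflated exactly to a minimum eigenvalue of 0.2. The support is
  the ground-truth edge set; positive definiteness is verified by Cholesky
  factorization.
- **Counts** (`simulate_counts`): logistic-normal-multinomial. Latent
  log-abundances are Gaussian with covariance `latent_scale^2 *
  inverse(precision)` around per-taxon baselines with spread
  `mean_log_spread = 1.5` — real communities are uneven over orders of
  magnitude, and an even community is both unrealistic and numerically
  atypical under CLR (uniform dropout then hits counts of hundreds of
  reads). `latent_scale = 2` matches the within-taxon log-fluctuations of
  abundant sediment ASVs. Library sizes are log-normal around `depth_mean =
  10,000` reads (CV 0.3, so stability selection faces heterogeneous
  depths); counts are multinomial; finally each count is zeroed
  independently with probability `zero_inflation = 0.1` (sampling zeros
  only — structural absences are deliberately not modeled, keeping the
  truth recoverable). At these defaults a 40-taxon table runs ~20–25%
  zeros. Scaling the latent field leaves partial correlations — the
  recovery target — untouched.
- **Depth profiles** (`simulate_metadata`): methane is a Gaussian bump
  centered in the SMTZ over a small background; sulfate decays
  monotonically with depth; sulfide and DIC accumulate; multiplicative
  log-normal noise on all four. One record per site x slice.
- **Planted signals** (`plant_balance_signal`): balanced binary labels;
  numerator taxa multiplied by `exp(effect)` in `high` samples, denominator
  taxa in `low` samples, re-rounded.

What the generator does **not** emulate: structural zeros, phylogenetic
correlation among taxa, chimeras/denoising artifacts, or any raw-read
process. Passing recovery tests therefore demonstrate correctness of the
estimators under the stated generative model, not performance guarantees on
arbitrary real sediment data.

## Reproducibility machinery

Every stochastic entry point takes a seed, evaluates under it, and restores
the caller's RNG state. Child seeds (per StARS subsample, attack iteration,
CV repeat, pipeline stage) derive from the master seed by a Lehmer-style
multiplicative mix — additive derivation would make the streams of
`(seed, i+1)` and `(seed+1, i)` identical, which measurably correlated
supposedly independent Monte-Carlo replicates during development. Pipeline
outputs embed the master seed and an MD5 hash of the configuration, and a
rerun with an identical configuration is bit-identical (no timestamps are
written).

## Problem sizes

The bundled validations run at: 40 taxa x 400 samples (x10 worlds) for edge
recovery; 20 x 300 (x5) for the null; 30 taxa x 200 samples x 100 repeats
for balance selection with a 20-permutation null ensemble; 10,000 attack
iterations on 10-node oracles and 2,000 on 50–55-node contrast graphs; and
a full pipeline pass at 60 taxa x 130 samples. These sizes give stable
medians and tight Monte-Carlo error for every asserted property; the
production-scale settings (10,000 attack iterations everywhere, 2,000
balance repeats) are single-parameter changes.

## Known limitations

- Edge weights are penalized regression coefficients, not calibrated
  partial correlations; compare magnitudes only within a network.
- Per-block CLR with very small blocks induces closure cliques (above).
- The latent adjustment is principal-component removal with eBIC rank
  scoring — a deliberate approximation to sparse-plus-low-rank estimation;
  the chosen rank is surfaced in provenance so users can inspect it.
- p-values from 10,000-iteration vulnerability comparisons are not
  biologically meaningful significance statements; use the percent change.
- The methane discretization is a proxy; where porewater chemistry is
  trustworthy, prefer `mode = "by_concentration"`.
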