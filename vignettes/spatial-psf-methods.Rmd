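---
title: "Pathway signal flow for spatial transcriptomics: models, parameters and design choices"
author: "SpatialPSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway signal flow for spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpatialPSF)
library(SummarizedExperiment)
```

# The model

SpatialPSF scores signalling-pathway activity for every spot of a
Visium-style spatial transcriptomics slide by *pathway signal flow* (PSF):
expression-derived fold-changes are propagated through a signed, directed
pathway graph, and the propagated signal at each *sink* (terminal,
out-degree-0) node is that branch's activity.

The ingredients, in pipeline order:

1. **Fold-change centring.** Per-spot counts are scaled to the median total
   count and `log1p`-transformed; fold-changes are formed on the linear
   scale as `fc(s, g) = (x(s, g) + c) / (mean_s x(s, g) + c)` with
   pseudocount `c` (default 1). A value of 1 is neutral: the spot expresses
   the gene at the tissue-wide average.
2. **Node mapping.** A gene node's value is the arithmetic mean of its
   measured member-gene fold-changes. Compound nodes, group placeholders
   and nodes with no measured gene get the neutral value 1, so unmeasured
   biology passes signal through untouched.
3. **Propagation.** Nodes are processed in topological order. An input
   (in-degree-0) node's signal is its own value. Any other node's signal is
   its own value multiplied by, for every incoming edge, the parent signal
   (activation) or its reciprocal (inhibition).
4. **Branch read-out.** Sink-node signals across all pathways form the
   spots-by-sinks activity matrix; `log2` of it is the feature space for
   clustering and all downstream statistics (0 = neutral).

## The multi-parent combination rule

The propagation rule is stated edge-wise (multiply for activation, divide
for inhibition). With several incoming edges we take the *product* of the
per-edge contributions, then multiply by the node's own value. The product
is the only combination that is associative, order-independent, and reduces
exactly to the chain rule on linear paths. A corollary worth knowing: when
two parallel routes lead from node *v* to a sink, *v*'s value enters the
sink signal squared. The alternative (averaging contributions) is less
sensitive to redundant wiring but no longer reduces to the chain rule; the
propagation core is a single function, so an alternative combiner can be
swapped in by advanced users.

Numerical safety: signals are clamped to `[1e-12, 1e12]` and the number of
clamped entries is reported as an attribute. Long inhibition chains on
near-zero fold-changes would otherwise overflow.

## Cycle handling and roles

Propagation needs an acyclic substrate, but curated pathways contain
feedback loops. `breakCycles()` runs a depth-first search from the current
in-degree-0 nodes (then any remaining nodes), always in lexicographic
node-id order, and removes every back edge it meets. This is deterministic,
keeps all forward signal routes, and records the removed edges for audit.
Input and sink roles are then recomputed on the acyclic edge set; an
isolated node is both input and sink and its activity is simply its own
fold-change.

# Statistics on branch activities

**Cluster-specific branches.** For each cluster, each sink's log2
activities are compared in-cluster vs all other spots with a Wilcoxon
rank-sum test; Benjamini–Hochberg adjustment is applied *within each
cluster* across all tested sinks, mirroring the per-comparison adjustment
convention of single-cell marker tests. Calls require `q < 0.05` and
|difference of mean log2 activities| above 0.25 (low stringency) or 0.5
(high stringency). The effect size is a difference of mean logs, not the
log of a ratio of means: activities are ratio-scale, and the mean of logs
is symmetric under inversion. A pathway is "significant" in a cluster when
at least one of its branches is — the package also reports the
significant-sink ratio and the sum of absolute branch effects per pathway.

The rank-sum implementation uses midranks; the p-value comes from the
exact conditional distribution (complete enumeration) when the pooled
sample is tiny, from the exact Mann–Whitney distribution when both groups
are below 50 without ties, and otherwise from the normal approximation
with tie-corrected variance and continuity correction.

**Spatial coordination.** For each branch, log2 activities clipped at zero
(up-regulation only) weight a Gaussian product-kernel density over the
slide, evaluated on a `grid_n` × `grid_n` grid (default 100) spanning the
coordinate bounding box with a 5% margin. Its Kullback–Leibler divergence
from the *uniform-weight spot density* — both floored at `epsilon = 1e-12`
and renormalized — measures how much the activity concentrates spatially.
Scott's rule on all spot coordinates supplies the bandwidth, shared by both
densities so the divergence reflects weighting only. Significance comes
from shuffling the weight vector across spot positions: this exchangeable
null preserves the weight distribution while destroying spatial
organization, and is the natural analogue of size-matched random gene sets
when the input is an activity vector rather than a gene list. The add-one
estimator `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` bounds p below by
`1/(n_perm + 1)`; with the default `n_perm = 1000` a feature can survive BH
adjustment across a few hundred features, which is why the default is not
smaller.

**Border crosstalk.** Spot adjacency is recovered from coordinates alone:
two spots are neighbours when their distance is at most 1.25 times the
minimum positive pairwise distance, which yields the six hexagonal lattice
neighbours for interior Visium spots and is robust to small jitter. Spots
whose neighbours all share their cluster are *core*; spots touching
cluster B are *border towards B*. Facing border groups of adjacent clusters
are compared per sink by OLS on a group indicator (the coefficient is
exactly the difference of group means; inference is the classical t-test on
the coefficient, BH-adjusted across sinks). Finally, a ligand–receptor
link is reported when a gene of a significantly up-regulated sink on one
side also sits in an input node of the other side's pathway *and* at least
one significant sink is reachable from that input by directed traversal.
The reachability guard is deliberately stricter than requiring pathway-wide
significance alone: it ties the link to a branch that is actually active
downstream of the matched receptor.

# Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `pseudocount` | 1 | added to numerator and denominator of the fold-change; damps ratios of weakly expressed genes |
| `aggregator` | mean | member-gene to node-value reduction (mean / median / geomean) |
| `n_pcs`, `k_neighbors`, `resolution` | 30, 20, 1.0 | PCA dimensionality, kNN graph degree, Louvain resolution |
| `lfc_low`, `lfc_high` | 0.25, 0.5 | |log2 fc| call thresholds (low / high stringency) |
| `alpha` | 0.05 | FDR level throughout |
| `bandwidth` | Scott's rule | per-axis KDE bandwidth, coordinate units |
| `grid_n` | 100 | KDE grid resolution per axis |
| `n_perm` | 1000 | permutations; min attainable p is 1/(n_perm+1) |
| `scale_factor` | 1.25 | adjacency threshold as a multiple of the lattice pitch |
| `min_group` | 10 | smallest core/border group kept for regression |

# The synthetic-data generator

`makeSpatialDataset()` emulates the features of a Visium experiment that
the method actually exploits: a hexagonal lattice (odd rows offset half a
pitch, row spacing √3/2), spatially contiguous cluster regions (Voronoi
cells of random lattice seeds), log-normal baseline gene abundances
(meanlog 0, sdlog 1), and negative-binomial counts (dispersion 0.5) at a
per-spot depth of 10,000 — the count scale of a spot pooling roughly ten
cells. Two hundred background genes accompany the pathway genes so that a
planted pathway shift stays a small fraction of each spot's transcriptome;
with a much smaller panel, per-spot depth normalization would visibly
absorb part of any planted effect (a compositional artifact, not a
property of the method).

Effects are planted *along a topology*: for a requested (pathway, sink,
cluster, effect), the generator walks from the sink back to an input node,
computes each path node's exact exponent in the sink signal (+1/−1 flips
per inhibitory edge, multiplicities accumulated across parallel routes by
the same dynamic program the propagation implies), splits the effect
evenly over the path nodes, and shifts every member gene of each node by
`effect / (L × exponent)` log2 units in the target region. Propagation on
noise-free means then moves the sink by exactly the requested effect;
under counting noise the recovered shift is unbiased but fluctuates with
the usual group-difference standard error.

What the generator does **not** emulate: spatial autocorrelation of
baseline expression within a region, cell-type mixtures within spots,
zero-inflation beyond NB sampling, and histology-correlated artifacts.
Passing tests therefore demonstrate correctness of the computation and
calibration under exchangeable noise — not robustness to every failure
mode of real tissue.

The ligand–receptor scenario (`makeLRScenario()`) uses two three-node
activation chains sharing one gene between the first chain's sink and the
second chain's input, on two half-plane regions. The planted shifts touch
only the *upstream* nodes of each chain, never the shared ligand gene
itself: the ligand's expression stays flat, so the second pathway is not
spuriously activated in the first region through its shared input, and the
recovered link is carried by topology and significance, not by the ligand's
own differential expression.

# Numerical and design notes

- **Normalization.** Regularized negative-binomial regression (SCT-style)
  is not re-implemented; median-total scaling + `log1p` is the default and
  `none` passes counts through. PSF consumes ratios, which are robust to
  the choice of monotone per-spot normalization; the fold-change step
  restores the linear scale via `expm1` before forming ratios, because
  multiplicative propagation presumes ratio-scale values centred at 1.
- **Whether to centre on the linear or the log scale** is exposed via
  `expm1Restore`; the default is linear, matching the multiplicative model.
- **Parallel edges** of opposite sign between the same node pair are kept;
  their contributions multiply (and cancel exactly when the parent signals
  are equal). Silent deduplication would lose curated information.
- **KGML subtype mapping**: activation and expression (including
  phosphorylation events annotated with activation) map to activation;
  inhibition and repression to inhibition; anything else (binding,
  indirect effects, state changes) is dropped with a counted warning —
  the propagation semantics define exactly two edge meanings.
- **Degenerate inputs**: all-negative log2 activities make a spatial
  feature unscorable (NA p rather than an error); all-tied rank-sum
  samples return p = 1 without dividing by a zero variance; constant
  feature columns are dropped before PCA with a warning.
- **Determinism**: every stochastic step takes an explicit seed;
  `cluster_louvain`, permutation tests and all generators reproduce
  bit-identical results for identical seeds, and pathway processing order
  never changes results.

# Problem sizes used in validation

The shipped test-suite and the acceptance script validate on: 200 random
signed DAGs of up to 12 nodes for the propagation oracle; 200 effect-free
tissues of 400 spots, 5 pathways and ~42 sinks for type-I calibration; 60
replicates of 100-spots-per-group planted-shift recovery (effect 1.0 log2
units, activity noise σ = 0.3); 200 features of 225 spots for permutation
calibration plus a 10%-of-tissue planted patch at `n_perm = 1000`; and the
full ligand–receptor scenario with both of its ablations on a 16 × 16
lattice. These sizes give Monte-Carlo standard errors small enough for the
stated tolerance bands while keeping a complete validation run in the
low minutes.

# Known limitations

- Cycle breaking is deterministic but order-dependent by construction;
  a different node labelling of the same topology can break a feedback
  loop at a different edge. The removed-edge audit trail makes this
  inspectable.
- The product rule amplifies redundant routes (see above); pathway
  curation that collapses duplicated cascades will change sink values.
- Branch tests treat spots as exchangeable within groups; spatial
  autocorrelation in real tissue makes the effective sample size smaller
  than the spot count, so borderline q-values should be read
  conservatively.
- ORA here is the plain hypergeometric tail on marker overlaps; it is the
  comparison baseline, not a replacement for topology-aware scoring.
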