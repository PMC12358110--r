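# SpatialPSF

Topology-aware pathway activity analysis for spot-based spatial
transcriptomics.

Gene-set scoring treats a pathway as a bag of genes. SpatialPSF instead
propagates expression changes through the pathway's wiring — a signed,
directed graph of activating and inhibiting interactions — so that every
*branch* (each terminal "sink" node) of every pathway gets its own activity
value in every Visium spot. The package is aimed at analysts of 10x
Visium-style data who want functional features that respect pathway
topology: for clustering tissue domains, for finding cluster-specific
deregulated branches, for mapping spatially coordinated signalling, and for
proposing ligand–receptor pathway links across the borders of adjacent
tissue domains.

## The method in brief

For spot *s* and gene *g*, expression is normalized (median-total scaling,
`log1p`), restored to the linear scale, and centred on the gene's
tissue-wide mean with pseudocount *c*:

    fc(s, g) = (x(s, g) + c) / (mean_s x(s, g) + c)

Fold-changes map onto pathway nodes (mean over a node's member genes;
unmeasured nodes are neutral at 1). With the pathway made acyclic and
nodes taken in topological order, the **pathway signal flow** at node *v*
is

    S(v) = value(v) × ∏ over incoming edges (u → v) of
              S(u)        if u activates v
              1 / S(u)    if u inhibits v

and an input node's signal is its own value. The signal at each sink node
is that branch's activity; `log2` activities (0 = neutral) feed all
downstream statistics:

- **cluster markers** — one-vs-all Wilcoxon rank-sum per (cluster, sink),
  BH-adjusted within cluster, called at |Δ mean log2| > 0.25 (low) or 0.5
  (high stringency);
- **spatial coordination** — clipped log2 activities weight a 2-D kernel
  density whose Kullback–Leibler divergence from the plain spot density is
  calibrated by weight permutation;
- **border crosstalk** — core vs border spots from the hex lattice
  adjacency, per-sink OLS between facing border groups, and
  ligand–receptor links where a significant sink's gene re-enters the
  neighbouring domain's pathway at an input node with a significant
  reachable sink.

Pathways are read from KEGG KGML or a plain two-TSV edge-list format; a
synthetic-data generator builds hex-lattice datasets with planted branch
effects and full ground truth.

## Worked example

Three random 8-node pathways, a 16 × 16 spot lattice with three contiguous
regions, and a +1.0 log2 effect planted on one branch of pathway `SYN001`
in region 0:

```r
library(SpatialPSF)

pathways <- lapply(1:3, function(i)
  makePathway(8, edgeProb = 0.35, seed = 100 + i,
              pathwayId = sprintf("SYN%03d", i)))
pathways[[1]]
#> PathwayGraph 'SYN001' (SYN001)
#>   8 nodes, 8 edges (6 activation, 2 inhibition)
#>   roles: 3 input, 3 sink nodes

sink1 <- sinkNodes(pathways[[1]])[1]
ds <- makeSpatialDataset(nSide = 16, clusters = 3, pathways = pathways,
  planted = list(list(pathway = "SYN001", sink = sink1,
                      cluster = 0L, effect = 1.0)), seed = 7)

fc  <- computeFoldChange(normalizeSpots(ds$expr))
act <- runPSF(fc, pathways)
act
#> class: ActivityMatrix
#> dim: 10 256
#> assays(1): activity
#> rownames(10): SYN001:n04 SYN001:n07 ... SYN003:n07 SYN003:n08

tab <- clusterBranchMarkers(act, ds$labels)
subset(tab, significant_high)[, c("cluster", "pathway_id", "sink", "log2_fc", "q")]
#>   cluster pathway_id sink   log2_fc            q
#> 1       0     SYN001  n04 0.8849702 0.0003234576
```

The ten sinks across the collection yield one high-stringency call:
exactly the planted branch (`SYN001:n04`) in the planted region, with an
estimated shift of 0.88 log2 units against the planted 1.0 (the gap is
counting noise at this depth) and q ≈ 3 × 10⁻⁴. The pathway-level
summary aggregates branch calls:

```r
summarizePathways(tab, "low")[1, ]
#>   cluster pathway_id n_sinks n_significant_sinks total_activity_change
#> 1       0     SYN001       3                   1              1.574027
#>   significant_ratio pathway_significant
#> 1         0.3333333                TRUE
```

A full run — reading a Visium directory, PSF, clustering, markers, spatial
statistics, border crosstalk, manifest — is one call
(`runPipeline(config)`), or from a shell:

```sh
Rscript inst/cli/psfspatial.R simulate --out data --scenario lr --seed 3
Rscript inst/cli/psfspatial.R run --visium data --pathways data/pathways \
    --labels data/labels.tsv --out results --seed 2
```

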