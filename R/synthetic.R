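#' Generate a random signed pathway DAG
#'
#' Nodes are placed in a fixed topological rank order and edges drawn only
#' from lower to higher rank, so the graph is acyclic by construction; each
#' edge is inhibitory with probability \code{inhibitionFrac}. Member gene
#' symbols are synthetic and unique to the pathway unless overridden, which
#' is how shared ligand/receptor genes are injected.
#'
#' @param nNodes number of nodes (>= 2, or 1 for a degenerate pathway).
#' @param edgeProb edge probability between each ranked pair.
#' @param inhibitionFrac probability an edge is inhibitory.
#' @param genesPerNode integer range (min, max) of member genes per node.
#' @param seed RNG seed; generation is deterministic given it.
#' @param pathwayId identifier (default derived from the seed).
#' @param memberOverrides named list node_id -> gene symbols replacing the
#'   synthetic members of those nodes.
#' @return a preprocessed (acyclic, role-annotated)
#'   \linkS4class{PathwayGraph}.
#' @export
makePathway <- function(nNodes, edgeProb = 0.3, inhibitionFrac = 0.25,
                        genesPerNode = c(1, 2), seed = 1L,
                        pathwayId = sprintf("SYN%04d", seed),
                        memberOverrides = list()) {
  stopifnot(nNodes >= 1, edgeProb > 0, edgeProb < 1)
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(nNodes))
    edges <- emptyEdgeFrame()
    for (attempt in seq_len(100)) {
      if (nNodes == 1) break
      pair <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
      draw <- stats::runif(nrow(pair)) < edgeProb
      if (!any(draw)) next
      sgn <- ifelse(stats::runif(sum(draw)) < inhibitionFrac,
                    "inhibition", "activation")
      edges <- data.frame(source = ids[pair[draw, 1]],
                          target = ids[pair[draw, 2]],
                          sign = sgn, stringsAsFactors = FALSE)
      break
    }
    if (nNodes > 1 && !nrow(edges))
      stop("could not generate a connected pathway in 100 attempts")
    ngenes <- sample(genesPerNode[1]:genesPerNode[2], nNodes, replace = TRUE)
    members <- lapply(seq_len(nNodes), function(i)
      sprintf("%s_%s_G%d", pathwayId, ids[i], seq_len(ngenes[i])))
    names(members) <- ids
    for (nm in names(memberOverrides))
      members[[nm]] <- memberOverrides[[nm]]
    nodes <- data.frame(node_id = ids, label = ids, node_class = "gene",
                        stringsAsFactors = FALSE)
    nodes$member_genes <- members
    g <- newPathwayGraph(pathwayId, pathwayId, nodes, edges)
    validObject(g)
    preprocessPathway(g)
  })
}

# hexagonal lattice of nSide x nSide spots with unit pitch: odd rows offset
# by half a pitch, row spacing sqrt(3)/2
hexLattice <- function(nSide) {
  row <- rep(seq_len(nSide) - 1L, each = nSide)
  col <- rep(seq_len(nSide) - 1L, times = nSide)
  data.frame(
    spot_id = sprintf("S%04d", seq_len(nSide^2)),
    array_row = row, array_col = col,
    y = row * sqrt(3) / 2,
    x = col + 0.5 * (row %% 2),
    stringsAsFactors = FALSE)
}

# contiguous cluster regions: Voronoi cells of `clusters` random lattice
# seeds under Euclidean distance
voronoiRegions <- function(lattice, clusters) {
  centers <- sample.int(nrow(lattice), clusters)
  d <- outer(seq_len(nrow(lattice)), centers, function(i, j)
    (lattice$y[i] - lattice$y[j])^2 + (lattice$x[i] - lattice$x[j])^2)
  max.col(-d, ties.method = "first") - 1L
}

# walk backwards from a sink to an in-degree-0 node, always taking the
# lexicographically smallest parent; returns the node path input -> sink
rootPathTo <- function(graph, sink) {
  ed <- pathwayEdges(graph)
  path <- sink
  v <- sink
  repeat {
    parents <- sort(unique(ed$source[ed$target == v]))
    if (!length(parents)) break
    v <- parents[1]
    path <- c(v, path)
  }
  path
}

# exact exponent with which each node's own value enters the sink signal
# under product propagation: exp(sink) = 1, and walking the DAG backwards
# exp(v) = sum over out-edges (v -> w) of sign * exp(w), so multiple
# forward paths accumulate (a diamond contributes its value squared) and
# opposite-sign parallel routes can cancel
nodeSinkExponents <- function(graph, sink) {
  ids <- pathwayNodes(graph)$node_id
  ed <- pathwayEdges(graph)
  ord <- topologicalOrder(graph)
  e <- stats::setNames(numeric(length(ids)), ids)
  e[sink] <- 1
  for (v in rev(ord)) {
    if (v == sink) next
    ix <- which(ed$source == v)
    if (length(ix))
      e[v] <- sum(ifelse(ed$sign[ix] == "inhibition", -1, 1) * e[ed$target[ix]])
  }
  e
}

# per-(cluster, gene) log2 shift matrix realizing the planted effects: the
# requested sink log2 effect is split evenly over the nodes of one
# input->sink path and each node's gene-level shift is divided by that
# node's exact sink exponent (sign-aware: an inhibitory route flips the
# required direction), then applied to every member gene
plantedGeneShifts <- function(pathways, planted, nClusters, genes) {
  shifts <- matrix(0, nClusters, length(genes),
                   dimnames = list(NULL, genes))
  paths_used <- list()
  for (p in planted) {
    g <- pathways[[p$pathway]]
    if (is.null(g)) stop("planted pathway not in collection: ", p$pathway)
    if (!p$sink %in% sinkNodes(g))
      stop(sprintf("planted node '%s' is not a sink of pathway '%s'",
                   p$sink, p$pathway))
    path <- rootPathTo(g, p$sink)
    if (!path[1] %in% inputNodes(g))
      stop("planted sink unreachable from any input node")
    nodes <- if (!is.null(p$nodes)) intersect(path, p$nodes) else path
    exps <- nodeSinkExponents(g, p$sink)[nodes]
    nodes <- nodes[exps != 0]      # cancelled routes cannot carry signal
    exps <- exps[exps != 0]
    if (!length(nodes))
      stop("planted path contributions cancel; choose another sink")
    per_node <- p$effect / length(nodes)
    mg <- memberGenes(g)
    for (nd in nodes) {
      gs <- intersect(mg[[nd]], genes)
      shifts[p$cluster + 1L, gs] <- shifts[p$cluster + 1L, gs] +
        per_node / exps[[nd]]
    }
    paths_used[[length(paths_used) + 1L]] <- path
  }
  attr(shifts, "paths") <- paths_used
  shifts
}

#' Generate a spatial expression dataset with planted branch deregulation
#'
#' Emulates a Visium-style experiment: a hexagonal lattice of
#' \code{nSide^2} spots, spatially contiguous cluster regions (Voronoi
#' cells of random lattice seeds), log-normal baseline gene abundances, and
#' negative-binomially over-dispersed counts at a per-spot depth around
#' \code{depthMean} (a spot pools roughly ten cells). For each planted
#' \code{list(pathway=, sink=, cluster=, effect=)} the genes along one
#' input-to-sink path are shifted (sign-aware: an inhibitory edge on the
#' path flips the required gene-level direction) so the sink's log2
#' activity changes by approximately \code{effect} in that cluster relative
#' to the rest of the tissue.
#'
#' @param nSide lattice side; the dataset has \code{nSide^2} spots.
#' @param clusters number of contiguous regions.
#' @param pathways list of preprocessed \linkS4class{PathwayGraph}s.
#' @param planted list of planted effects (possibly empty); each element a
#'   list with \code{pathway}, \code{sink}, \code{cluster} (0-based) and
#'   \code{effect} (log2 units). An optional \code{nodes} element restricts
#'   the shift to a subset of path nodes.
#' @param depthMean expected total count per spot.
#' @param noiseSd extra spot x gene log-normal noise (0 = none).
#' @param dispersion negative-binomial dispersion (1/size).
#' @param nBackgroundGenes unrelated genes added to the panel.
#' @param seed RNG seed; output is deterministic given it.
#' @return list with \code{expr} (\linkS4class{SpotExpression}),
#'   \code{labels} (named 0-based cluster vector) and \code{truth} (list:
#'   \code{region_masks}, \code{deregulated} data.frame,
#'   \code{lr_links_planted}).
#' @export
makeSpatialDataset <- function(nSide = 20, clusters = 4, pathways,
                               planted = list(), depthMean = 10000,
                               noiseSd = 0, dispersion = 0.5,
                               nBackgroundGenes = 200, seed = 1L) {
  stopifnot(clusters >= 1, nSide >= 2)
  if (is(pathways, "PathwayGraph")) pathways <- list(pathways)
  names(pathways) <- vapply(pathways, pathwayId, character(1))
  withr::with_seed(seed, {
    lattice <- hexLattice(nSide)
    n <- nrow(lattice)
    labels <- if (clusters == 1) rep(0L, n) else voronoiRegions(lattice, clusters)
    names(labels) <- lattice$spot_id

    genes <- unique(unlist(lapply(pathways, function(g)
      unlist(memberGenes(g)))))
    if (nBackgroundGenes > 0)
      genes <- c(genes, sprintf("BG_G%03d", seq_len(nBackgroundGenes)))
    shifts <- plantedGeneShifts(pathways, planted, clusters, genes)

    base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
    prop <- base / sum(base)
    mu0 <- outer(prop, rep(depthMean, n))          # genes x spots
    fold <- 2^t(shifts[labels + 1L, , drop = FALSE])
    mu <- mu0 * fold
    if (noiseSd > 0)
      mu <- mu * exp(matrix(stats::rnorm(length(mu), 0, noiseSd), nrow(mu)))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu),
                     dimnames = list(genes, lattice$spot_id))

    se <- SummarizedExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(
        coord_y = lattice$y, coord_x = lattice$x,
        array_row = lattice$array_row, array_col = lattice$array_col,
        in_tissue = rep(TRUE, n), row.names = lattice$spot_id))
    expr <- methods::new("SpotExpression", se)

    masks <- lapply(seq_len(clusters) - 1L, function(cl)
      stats::setNames(labels == cl, names(labels)))
    names(masks) <- as.character(seq_len(clusters) - 1L)
    dereg <- if (length(planted)) data.frame(
      pathway_id = vapply(planted, `[[`, character(1), "pathway"),
      sink = vapply(planted, `[[`, character(1), "sink"),
      cluster = vapply(planted, function(p) as.integer(p$cluster), integer(1)),
      effect = vapply(planted, function(p) as.numeric(p$effect), numeric(1)),
      stringsAsFactors = FALSE)
    else data.frame(pathway_id = character(), sink = character(),
                    cluster = integer(), effect = numeric())
    truth <- list(region_masks = masks, deregulated = dereg,
                  lr_links_planted = list())
    attr(labels, "source") <- "external"
    list(expr = expr, labels = labels, truth = truth)
  })
}

#' Ligand-receptor ground-truth scenario
#'
#' Two half-plane cluster regions on the lattice and two chain pathways
#' sharing one gene: the ligand gene is the only member of pathway LR_P1's
#' sink and also of pathway LR_P2's input node. Pathway LR_P1 is activated
#' in cluster 0 and LR_P2 in cluster 1, by shifting the genes of the
#' upstream path nodes only, so the shared ligand's own expression stays
#' flat and the activation is carried by topology. Running the border
#' crosstalk pipeline on this dataset must recover exactly the one planted
#' sink-to-input link.
#'
#' @param seed RNG seed.
#' @param nSide lattice side (default 16).
#' @param effect planted log2 sink effect on each side; 0 ablates all
#'   significance (no links expected).
#' @param dropSharedInput ablation: replace the shared gene in LR_P2's input
#'   node by a private gene (no links expected).
#' @param depthMean,dispersion count model parameters (see
#'   \code{\link{makeSpatialDataset}}).
#' @return list with \code{expr}, \code{labels}, \code{pathways} and
#'   \code{truth}; \code{truth$lr_links_planted} names the expected link.
#' @export
makeLRScenario <- function(seed = 1L, nSide = 16, effect = 2.5,
                           dropSharedInput = FALSE, depthMean = 10000,
                           dispersion = 0.2) {
  shared <- "LIG1"
  p1 <- makePathwayChain("LR_P1", c("i1", "m1", "s1"),
                         members = list(i1 = c("LR_P1_i1_G1", "LR_P1_i1_G2"),
                                        m1 = c("LR_P1_m1_G1", "LR_P1_m1_G2"),
                                        s1 = shared))
  p2_input <- if (dropSharedInput) "LR_P2_r1_G1" else shared
  p2 <- makePathwayChain("LR_P2", c("r1", "m2", "s2"),
                         members = list(r1 = p2_input,
                                        m2 = c("LR_P2_m2_G1", "LR_P2_m2_G2"),
                                        s2 = c("LR_P2_s2_G1", "LR_P2_s2_G2")))
  pathways <- list(p1, p2)
  planted <- if (effect != 0) list(
    # upstream nodes only: the shared ligand gene itself is left unshifted
    list(pathway = "LR_P1", sink = "s1", cluster = 0L, effect = effect,
         nodes = c("i1", "m1")),
    list(pathway = "LR_P2", sink = "s2", cluster = 1L, effect = effect,
         nodes = c("m2", "s2")))
  else list()
  # two half-plane cluster regions split at the median x coordinate
  lattice <- hexLattice(nSide)
  labels <- stats::setNames(as.integer(lattice$x > stats::median(lattice$x)),
                            lattice$spot_id)
  ds <- makeSpatialDatasetWithLabels(nSide, labels, pathways, planted,
                                     depthMean, dispersion, seed)
  ds$pathways <- pathways
  ds$truth$lr_links_planted <- if (effect != 0 && !dropSharedInput)
    list(list(gene = shared, from_pathway = "LR_P1", from_sink = "s1",
              to_pathway = "LR_P2", to_input = "r1"))
  else list()
  ds
}

# activation chain pathway with explicit member genes
makePathwayChain <- function(pathwayId, nodeIds, members) {
  nodes <- data.frame(node_id = nodeIds, label = nodeIds,
                      node_class = "gene", stringsAsFactors = FALSE)
  nodes$member_genes <- lapply(nodeIds, function(id) members[[id]])
  k <- length(nodeIds)
  edges <- if (k > 1)
    data.frame(source = nodeIds[-k], target = nodeIds[-1],
               sign = "activation", stringsAsFactors = FALSE)
  else emptyEdgeFrame()
  preprocessPathway(newPathwayGraph(pathwayId, pathwayId, nodes, edges))
}

# variant of makeSpatialDataset that takes explicit labels instead of
# sampling Voronoi regions (used by the LR scenario)
makeSpatialDatasetWithLabels <- function(nSide, labels, pathways, planted,
                                         depthMean, dispersion, seed) {
  names(pathways) <- vapply(pathways, pathwayId, character(1))
  withr::with_seed(seed + 1000L, {
    lattice <- hexLattice(nSide)
    n <- nrow(lattice)
    labels <- labels[lattice$spot_id]
    nClusters <- max(labels) + 1L
    genes <- unique(unlist(lapply(pathways, function(g)
      unlist(memberGenes(g)))))
    genes <- c(genes, sprintf("BG_G%03d", seq_len(200)))
    shifts <- plantedGeneShifts(pathways, planted, nClusters, genes)
    base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
    prop <- base / sum(base)
    mu <- outer(prop, rep(depthMean, n)) * 2^t(shifts[labels + 1L, , drop = FALSE])
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu),
                     dimnames = list(genes, lattice$spot_id))
    se <- SummarizedExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(
        coord_y = lattice$y, coord_x = lattice$x,
        array_row = lattice$array_row, array_col = lattice$array_col,
        in_tissue = rep(TRUE, n), row.names = lattice$spot_id))
    masks <- lapply(seq_len(nClusters) - 1L, function(cl)
      stats::setNames(labels == cl, names(labels)))
    names(masks) <- as.character(seq_len(nClusters) - 1L)
    dereg <- if (length(planted)) data.frame(
      pathway_id = vapply(planted, `[[`, character(1), "pathway"),
      sink = vapply(planted, `[[`, character(1), "sink"),
      cluster = vapply(planted, function(p) as.integer(p$cluster), integer(1)),
      effect = vapply(planted, function(p) as.numeric(p$effect), numeric(1)),
      stringsAsFactors = FALSE)
    else data.frame(pathway_id = character(), sink = character(),
                    cluster = integer(), effect = numeric())
    attr(labels, "source") <- "external"
    list(expr = methods::new("SpotExpression", se), labels = labels,
         truth = list(region_masks = masks, deregulated = dereg,
                      lr_links_planted = list()))
  })
}

#' Write a synthetic dataset through the standard file interfaces
#'
#' Emits the Visium triplet + positions CSV (via \code{\link{writeVisium}}),
#' the cluster labels TSV and the ground truth JSON, so the whole pipeline
#' can be exercised from files.
#'
#' @param dataset a \code{\link{makeSpatialDataset}} /
#'   \code{\link{makeLRScenario}} result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVisium(dataset$expr, dir)
  writeClusterLabels(dataset$labels, file.path(dir, "labels.tsv"))
  truth <- dataset$truth
  truth$region_masks <- lapply(truth$region_masks, function(m)
    names(m)[m])      # spot-id lists serialize more compactly than masks
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  if (!is.null(dataset$pathways))
    for (g in dataset$pathways)
      writePathwayTables(g, file.path(dir, "pathways", pathwayId(g)))
  invisible(dir)
}
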