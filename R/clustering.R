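#' Cluster spots on a feature matrix
#'
#' Standard modularity-based graph clustering: features are
#' column-standardized, projected onto principal components, a symmetric
#' k-nearest-neighbour graph is built on Euclidean distance, and communities
#' are found by Louvain modularity optimization at the given resolution.
#' For pathway-activity clustering pass log2 activities (0 = neutral); for
#' expression clustering pass the normalized matrix restricted to top
#' variable genes (see \code{\link{topVariableFeatures}}).
#'
#' @param features spots x d numeric matrix (d >= 2).
#' @param nPCs number of principal components (capped at the number of
#'   non-constant features).
#' @param kNeighbors neighbours per spot; must be < number of spots.
#' @param resolution Louvain resolution; larger values give more clusters.
#' @param seed RNG seed (community detection is seeded; identical seeds give
#'   identical labels).
#' @return named integer vector of 0-based contiguous cluster labels
#'   (names = spot ids), with the parameters attached as attribute
#'   \code{"parameters"} and \code{"source"} set to "features".
#' @export
clusterFeatures <- function(features, nPCs = 30, kNeighbors = 20,
                            resolution = 1.0, seed = 0L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (ncol(features) < 2) stop("need at least 2 feature columns")
  if (kNeighbors > n - 1)
    stop(sprintf("kNeighbors (%d) must be < number of spots (%d)", kNeighbors, n))
  sds <- apply(features, 2, stats::sd)
  if (all(sds == 0)) stop("all feature columns are constant")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s) dropped")
    features <- features[, sds > 0, drop = FALSE]
  }
  pcs <- min(nPCs, ncol(features), n - 1)
  pr <- stats::prcomp(features, center = TRUE, scale. = TRUE, rank. = pcs)
  emb <- pr$x

  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  # union-of-kNN undirected graph
  nn <- apply(d, 1, function(r) order(r)[seq_len(kNeighbors)])
  el <- cbind(rep(seq_len(n), each = kNeighbors), as.vector(nn))
  el <- t(apply(el, 1, sort))
  el <- unique(el)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- rownames(features)
  attr(labels, "source") <- "features"
  attr(labels, "parameters") <- list(n_pcs = pcs, k_neighbors = kNeighbors,
                                     resolution = resolution, seed = seed)
  labels
}

#' Indices of the most variable features
#'
#' @param mat genes x spots matrix.
#' @param n number of features to keep (default 2000).
#' @return character vector of row names, ordered by decreasing variance.
#' @export
topVariableFeatures <- function(mat, n = 2000) {
  v <- apply(mat, 1, stats::var)
  head(rownames(mat)[order(v, decreasing = TRUE)], n)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same spots,
#' computed from the contingency table under the permutation model.
#' 1 = identical partitions, ~0 = independent, negative = less agreement
#' than expected by chance.
#'
#' @param a,b labelings: named vectors over the same spot set, or unnamed
#'   vectors of equal length (taken as aligned).
#' @return a real in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("labelings cover different spot sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("labelings have different lengths and no names to align by")
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # degenerate: single cluster etc.
  (sum_ij - expected) / (max_index - expected)
}

#' Read / write cluster label TSVs
#'
#' TSV with columns \code{spot_id}, \code{label}; used to import external
#' (e.g. spatially-aware) clusterings for comparison.
#'
#' @param path TSV path.
#' @return named integer label vector with \code{source = "external"}.
#' @export
readClusterLabels <- function(path) {
  df <- utils::read.delim(path)
  labels <- stats::setNames(as.integer(df$label), df$spot_id)
  attr(labels, "source") <- "external"
  labels
}

#' @rdname readClusterLabels
#' @param labels named integer label vector.
#' @export
writeClusterLabels <- function(labels, path) {
  utils::write.table(
    data.frame(spot_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
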