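#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of marker-gene overlap with each gene set,
#' restricted to the supplied universe; BH adjustment across sets. Gene sets
#' disjoint from the universe are excluded with a warning.
#'
#' @param markers character vector of marker genes (intersected with the
#'   universe; must not be empty after intersection).
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @param universe character vector of all testable genes.
#' @return data.frame per set: \code{set}, \code{set_size} (in-universe),
#'   \code{overlap}, \code{p}, \code{q}.
#' @export
oraHypergeometric <- function(markers, geneSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  markers <- intersect(unique(markers), universe)
  if (!length(markers)) stop("no marker genes in the universe")
  sets <- lapply(geneSets, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " gene set(s) disjoint from the universe excluded: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene set overlaps the universe")
  N <- length(universe); n <- length(markers)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, markers)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set = names(sets), set_size = as.integer(K),
             overlap = as.integer(k), p = p, q = bhAdjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of gene symbol vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Cluster-specific marker genes by rank-sum testing
#'
#' Differential expression companion to \code{\link{clusterBranchMarkers}}:
#' one-vs-all Wilcoxon tests on log-normalized expression, BH within
#' cluster, thresholds on the difference of mean log2 expression.
#'
#' @param norm genes x spots log1p-normalized matrix.
#' @param labels named integer cluster labels.
#' @param lfc |log2 fc| threshold (0.5 low / 1 high stringency convention).
#' @param alpha FDR level.
#' @param minSpots minimum cluster size.
#' @return data.frame per (cluster, gene) with \code{log2_fc}, \code{p},
#'   \code{q}, \code{significant}.
#' @export
clusterMarkerGenes <- function(norm, labels, lfc = 0.5, alpha = 0.05,
                               minSpots = 3) {
  norm <- as.matrix(norm)
  if (!is.null(names(labels))) labels <- labels[colnames(norm)]
  l2 <- norm / log(2)     # log1p counts -> log2(1 + x) scale
  clusters <- sort(unique(as.integer(labels)))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  res <- list()
  for (cl in clusters) {
    in_cl <- as.integer(labels) == cl
    if (sum(in_cl) < minSpots) next
    sm <- t(vapply(seq_len(nrow(l2)), function(i) {
      t <- rankSumTest(l2[i, in_cl], l2[i, !in_cl])
      c(mean(l2[i, in_cl]) - mean(l2[i, !in_cl]), t$p)
    }, numeric(2)))
    q <- bhAdjust(sm[, 2])
    res[[length(res) + 1L]] <- data.frame(
      cluster = cl, gene = rownames(l2), log2_fc = sm[, 1],
      p = sm[, 2], q = q,
      significant = q < alpha & abs(sm[, 1]) > lfc,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare pathway calls between methods
#'
#' Per cluster, the sets of pathways called significant by each method and
#' all pairwise (and, with a third method, triple) intersection counts.
#'
#' @param psf a \code{\link{summarizePathways}} result (uses
#'   \code{pathway_significant}).
#' @param ora data.frame with columns \code{cluster}, \code{set} (pathway
#'   id) and either \code{significant} or \code{q} (then q < alpha calls).
#' @param third optional data.frame with columns \code{cluster},
#'   \code{pathway_id}, \code{significant} from an external tool.
#' @param alpha significance level used when only q-values are supplied.
#' @return data.frame per cluster with per-method call counts and
#'   intersection counts; the call sets themselves are attached as
#'   attribute \code{"calls"}.
#' @export
compareMethodCalls <- function(psf, ora, third = NULL, alpha = 0.05) {
  psf_calls <- split(psf$pathway_id[psf$pathway_significant],
                     psf$cluster[psf$pathway_significant])
  ora_sig <- if ("significant" %in% names(ora)) ora$significant else ora$q < alpha
  ora_id <- if ("set" %in% names(ora)) ora$set else ora$pathway_id
  ora_calls <- split(ora_id[ora_sig], ora$cluster[ora_sig])
  third_calls <- if (!is.null(third))
    split(third$pathway_id[third$significant], third$cluster[third$significant])
  clusters <- sort(unique(c(names(psf_calls), names(ora_calls),
                            names(third_calls))))
  rows <- lapply(clusters, function(cl) {
    a <- unique(psf_calls[[cl]]); b <- unique(ora_calls[[cl]])
    c3 <- unique(third_calls[[cl]])
    r <- data.frame(cluster = cl, n_psf = length(a), n_ora = length(b),
                    n_psf_ora = length(intersect(a, b)),
                    stringsAsFactors = FALSE)
    if (!is.null(third)) {
      r$n_third <- length(c3)
      r$n_psf_third <- length(intersect(a, c3))
      r$n_ora_third <- length(intersect(b, c3))
      r$n_all <- length(Reduce(intersect, list(a, b, c3)))
    }
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "calls") <- list(psf = psf_calls, ora = ora_calls,
                             third = third_calls)
  out
}
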