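#' Spot adjacency on the lattice
#'
#' Neighbours are spot pairs with Euclidean distance at most
#' \code{scaleFactor} times the minimum positive pairwise distance. On a
#' regular hexagonal Visium-style lattice the default factor recovers the
#' six lattice neighbours of every interior spot.
#'
#' @param coords spots x 2 coordinate matrix with rownames = spot ids.
#' @param scaleFactor multiple of the lattice pitch (default 1.25).
#' @return list with \code{neighbors} (named list of spot-id vectors,
#'   symmetric, no self-neighbours) and \code{distance_threshold}.
#' @export
spotAdjacency <- function(coords, scaleFactor = 1.25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 spots")
  ids <- rownames(coords) %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  dmin <- min(d)
  if (dmin == 0) stop("duplicate spot coordinates")
  thr <- scaleFactor * dmin
  nb <- lapply(seq_len(n), function(i) ids[d[i, ] <= thr])
  names(nb) <- ids
  list(neighbors = nb, distance_threshold = thr)
}

#' Core / border classification of spots
#'
#' A spot is \emph{core} when every lattice neighbour belongs to its own
#' cluster, and \emph{border} towards cluster B when at least one neighbour
#' belongs to B. Each cluster yields one core group plus one border group
#' per adjacent cluster; a spot touching several clusters joins each
#' corresponding border group. Groups smaller than \code{minGroup} are
#' dropped with a warning.
#'
#' @param labels named integer cluster labels.
#' @param adj a \code{\link{spotAdjacency}} result.
#' @param minGroup minimum group size to keep.
#' @return data.frame with columns \code{spot_id}, \code{cluster},
#'   \code{role} ("core"/"border"), \code{adjacent_cluster} (NA for core).
#' @export
classifyCoreBorder <- function(labels, adj, minGroup = 10) {
  nb <- adj$neighbors
  ids <- names(nb)
  if (!all(ids %in% names(labels)))
    stop("labels missing for some spots in the adjacency")
  lab <- labels[ids]
  rows <- list()
  for (i in seq_along(ids)) {
    own <- lab[[i]]
    nbl <- lab[nb[[i]]]
    foreign <- unique(nbl[nbl != own])
    if (!length(foreign)) {
      rows[[length(rows) + 1L]] <- data.frame(
        spot_id = ids[i], cluster = own, role = "core",
        adjacent_cluster = NA_integer_, stringsAsFactors = FALSE)
    } else {
      for (f in foreign)
        rows[[length(rows) + 1L]] <- data.frame(
          spot_id = ids[i], cluster = own, role = "border",
          adjacent_cluster = f, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  key <- paste(out$cluster, out$role, out$adjacent_cluster)
  sizes <- table(key)
  small <- names(sizes)[sizes < minGroup]
  if (length(small)) {
    warning(length(small), " group(s) below minGroup dropped")
    out <- out[!key %in% small, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Compare branch activities between two spot groups
#'
#' Per sink node, ordinary least squares of log2 activity on a binary group
#' indicator (group B = 1): the coefficient equals the difference of group
#' means (B minus A), tested two-sided via its t statistic; BH adjustment
#' across sinks.
#'
#' @param activity an \linkS4class{ActivityMatrix} or sinks x spots matrix.
#' @param groupA,groupB disjoint character vectors of spot ids, each with at
#'   least 3 spots.
#' @param alpha FDR level used for the \code{significant} flag.
#' @return data.frame per sink: \code{pathway_id}, \code{sink},
#'   \code{coefficient}, \code{p}, \code{q}, \code{significant}.
#' @export
compareGroups <- function(activity, groupA, groupB, alpha = 0.05) {
  am <- activityAsMatrix(activity)
  idx <- activitySinkIndex(activity, am)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap")
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("each group needs at least 3 spots")
  missing <- setdiff(c(groupA, groupB), colnames(am))
  if (length(missing))
    stop("spots absent from activity matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  la <- log2(am)
  na <- length(groupA); nb <- length(groupB)
  df <- na + nb - 2
  res <- t(vapply(seq_len(nrow(la)), function(i) {
    a <- la[i, groupA]; b <- la[i, groupB]
    coef <- mean(b) - mean(a)
    ssr <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    se <- sqrt(ssr / df * (1 / na + 1 / nb))
    if (se == 0) {
      p <- if (coef == 0) 1 else 0
    } else {
      p <- 2 * stats::pt(-abs(coef / se), df)
    }
    c(coef, p)
  }, numeric(2)))
  q <- bhAdjust(res[, 2])
  data.frame(pathway_id = idx$pathway_id, sink = idx$node_id,
             coefficient = res[, 1], p = res[, 2], q = q,
             significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ligand-receptor pathway links between adjacent groups
#'
#' A link is emitted when a gene of a significant sink node in one group's
#' pathway also belongs to an input node of a pathway in the adjacent group
#' from which at least one significant sink is reachable by directed
#' traversal. Both directions (A to B and B to A) are scanned.
#'
#' @param sigA,sigB data.frames of significant sinks per group, with columns
#'   \code{pathway_id} and \code{sink} (e.g. filtered
#'   \code{\link{compareGroups}} output).
#' @param pathways list of preprocessed \linkS4class{PathwayGraph}s covering
#'   the pathway ids referenced.
#' @return data.frame of links: \code{gene}, \code{from_pathway},
#'   \code{from_sink}, \code{to_pathway}, \code{to_input},
#'   \code{direction} ("A->B" or "B->A"). Zero rows when nothing matches.
#' @export
ligandReceptorLinks <- function(sigA, sigB, pathways) {
  if (is(pathways, "PathwayGraph")) pathways <- list(pathways)
  names(pathways) <- vapply(pathways, pathwayId, character(1))
  scan <- function(sig_from, sig_to, direction) {
    out <- list()
    if (!nrow(sig_from) || !nrow(sig_to)) return(out)
    for (i in seq_len(nrow(sig_from))) {
      gfrom <- pathways[[sig_from$pathway_id[i]]]
      if (is.null(gfrom)) next
      mg <- memberGenes(gfrom)[[sig_from$sink[i]]]
      if (!length(mg)) next
      for (pg in pathways) {
        sinks_to <- sig_to$sink[sig_to$pathway_id == pathwayId(pg)]
        if (!length(sinks_to)) next
        for (inp in inputNodes(pg)) {
          shared <- intersect(mg, memberGenes(pg)[[inp]])
          if (!length(shared)) next
          reach <- reachableFrom(pg, inp)
          if (!length(intersect(reach, sinks_to))) next
          for (g in shared)
            out[[length(out) + 1L]] <- data.frame(
              gene = g,
              from_pathway = sig_from$pathway_id[i],
              from_sink = sig_from$sink[i],
              to_pathway = pathwayId(pg), to_input = inp,
              direction = direction, stringsAsFactors = FALSE)
        }
      }
    }
    out
  }
  rows <- c(scan(sigA, sigB, "A->B"), scan(sigB, sigA, "B->A"))
  if (!length(rows))
    return(data.frame(gene = character(), from_pathway = character(),
                      from_sink = character(), to_pathway = character(),
                      to_input = character(), direction = character(),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$direction, out$from_pathway, out$from_sink,
                   out$to_pathway, out$to_input, out$gene), ]
  rownames(out) <- NULL
  out
}

# nodes reachable from `from` by directed BFS (including itself)
reachableFrom <- function(graph, from) {
  ed <- pathwayEdges(graph)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(ed$target[ed$source %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Border crosstalk analysis
#'
#' End-to-end wrapper: builds the lattice adjacency, classifies core/border
#' spots, and for every adjacent cluster pair compares the two facing border
#' groups (\code{\link{compareGroups}}); sinks significantly higher on one
#' side define that side's significant pathways, and
#' \code{\link{ligandReceptorLinks}} matches sink genes against input nodes
#' across the border.
#'
#' @param activity an \linkS4class{ActivityMatrix}.
#' @param labels named integer cluster labels.
#' @param coords spots x 2 coordinate matrix (rownames = spot ids).
#' @param pathways list of preprocessed \linkS4class{PathwayGraph}s.
#' @param alpha FDR level.
#' @param minGroup minimum border-group size.
#' @param scaleFactor adjacency threshold factor.
#' @return list with \code{groups} (core/border table), \code{comparisons}
#'   (per-pair test tables) and \code{links} (combined link table with
#'   \code{cluster_a}/\code{cluster_b} columns).
#' @export
borderCrosstalk <- function(activity, labels, coords, pathways,
                            alpha = 0.05, minGroup = 10, scaleFactor = 1.25) {
  adj <- spotAdjacency(coords, scaleFactor)
  groups <- classifyCoreBorder(labels, adj, minGroup)
  borders <- groups[groups$role == "border", ]
  pairs <- if (nrow(borders))
    unique(t(apply(cbind(borders$cluster, borders$adjacent_cluster), 1, sort)))
  else matrix(integer(), ncol = 2)
  comparisons <- list()
  links <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ga <- borders$spot_id[borders$cluster == a & borders$adjacent_cluster == b]
    gb <- borders$spot_id[borders$cluster == b & borders$adjacent_cluster == a]
    if (length(ga) < 3 || length(gb) < 3) next
    cmp <- compareGroups(activity, ga, gb, alpha)
    comparisons[[paste(a, b, sep = "|")]] <- cmp
    sigA <- cmp[cmp$significant & cmp$coefficient < 0, c("pathway_id", "sink")]
    sigB <- cmp[cmp$significant & cmp$coefficient > 0, c("pathway_id", "sink")]
    lk <- ligandReceptorLinks(sigA, sigB, pathways)
    if (nrow(lk)) {
      lk$cluster_a <- a
      lk$cluster_b <- b
      links[[length(links) + 1L]] <- lk
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(gene = character(), from_pathway = character(),
               from_sink = character(), to_pathway = character(),
               to_input = character(), direction = character(),
               cluster_a = integer(), cluster_b = integer(),
               stringsAsFactors = FALSE)
  list(groups = groups, comparisons = comparisons, links = links)
}
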