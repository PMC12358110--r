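#' Break cycles in a pathway graph
#'
#' Signal propagation requires an acyclic substrate. Cycles are broken by
#' depth-first search started from the current in-degree-0 nodes (then from
#' any remaining unvisited nodes), both in lexicographic node-id order, with
#' out-edges explored in lexicographic target order. Every back edge
#' encountered (including self-loops) is removed and recorded in
#' \code{removedEdges}. The procedure is deterministic and preserves all
#' forward signal paths.
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @return the graph with an acyclic edge set; removed edges appended to
#'   \code{removedEdges(graph)}. An acyclic input is returned unchanged.
#' @export
breakCycles <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  ed <- graph@edges
  ids <- graph@nodes$node_id
  if (!nrow(ed)) return(graph)

  # adjacency as edge-row indices, out-edges sorted by (target, sign)
  out <- split(seq_len(nrow(ed)), factor(ed$source, levels = ids))
  out <- lapply(out, function(ix) ix[order(ed$target[ix], ed$sign[ix])])

  indeg <- table(factor(ed$target, levels = ids))
  roots <- sort(ids[indeg == 0])
  order_all <- c(roots, sort(setdiff(ids, roots)))

  color <- stats::setNames(rep.int(0L, length(ids)), ids) # 0 white 1 gray 2 black
  drop <- logical(nrow(ed))

  for (root in order_all) {
    if (color[root] != 0L) next
    # iterative DFS: stack of (node, pointer into its out-edge list)
    stack_node <- root
    stack_ptr <- 1L
    color[root] <- 1L
    while (length(stack_node)) {
      top <- length(stack_node)
      v <- stack_node[top]
      eix <- out[[v]]
      p <- stack_ptr[top]
      if (p > length(eix)) {
        color[v] <- 2L
        stack_node <- stack_node[-top]
        stack_ptr <- stack_ptr[-top]
        next
      }
      stack_ptr[top] <- p + 1L
      e <- eix[p]
      if (drop[e]) next
      w <- ed$target[e]
      if (color[w] == 1L) {            # back edge: breaks a cycle
        drop[e] <- TRUE
      } else if (color[w] == 0L) {
        color[w] <- 1L
        stack_node <- c(stack_node, w)
        stack_ptr <- c(stack_ptr, 1L)
      }
    }
  }

  if (any(drop)) {
    removed <- ed[drop, , drop = FALSE]
    rownames(removed) <- NULL
    graph@removedEdges <- rbind(graph@removedEdges, removed)
    graph@edges <- ed[!drop, , drop = FALSE]
    rownames(graph@edges) <- NULL
  }
  graph
}

#' Assign input and sink roles
#'
#' On the (acyclic) preprocessed edge set, input nodes are the in-degree-0
#' nodes where propagation starts from the node's own fold-change value, and
#' sink (terminal) nodes are the out-degree-0 nodes whose propagated signal
#' is the branch activity readout. An isolated node is both input and sink.
#'
#' @param graph an acyclic \linkS4class{PathwayGraph}.
#' @return the graph with \code{inputNodes} and \code{sinkNodes} filled in.
#' @export
assignRoles <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  ids <- graph@nodes$node_id
  if (!length(ids)) stop("cannot assign roles: pathway has zero nodes")
  if (!isAcyclic(graph))
    stop("graph contains a cycle; run breakCycles() first")
  ed <- graph@edges
  indeg <- table(factor(ed$target, levels = ids))
  outdeg <- table(factor(ed$source, levels = ids))
  graph@inputNodes <- ids[indeg == 0]
  graph@sinkNodes <- ids[outdeg == 0]
  graph
}

#' Preprocess a pathway for signal propagation
#'
#' Convenience wrapper: \code{\link{breakCycles}} followed by
#' \code{\link{assignRoles}}.
#'
#' @param graph a parsed \linkS4class{PathwayGraph}.
#' @return an acyclic, role-annotated graph ready for \code{\link{runPSF}}.
#' @export
preprocessPathway <- function(graph) assignRoles(breakCycles(graph))

#' Test whether a pathway graph is acyclic
#'
#' Kahn peeling on the current edge set.
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @return TRUE if no directed cycle exists.
#' @export
isAcyclic <- function(graph) {
  !is.null(topologicalOrder(graph, strict = FALSE))
}

# Kahn's algorithm with lexicographic tie-break; NULL on a cycle unless
# strict, in which case it errors.
topologicalOrder <- function(graph, strict = TRUE) {
  ids <- graph@nodes$node_id
  ed <- graph@edges
  indeg <- stats::setNames(as.integer(table(factor(ed$target, levels = ids))), ids)
  out <- split(ed$target, factor(ed$source, levels = ids))
  avail <- sort(ids[indeg == 0L])
  ord <- character(0)
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(ord) < length(ids)) {
    if (strict) stop("graph contains a cycle; run breakCycles() first")
    return(NULL)
  }
  ord
}
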