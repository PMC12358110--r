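#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

VALID_EDGE_SIGNS <- c("activation", "inhibition")
VALID_NODE_CLASSES <- c("gene", "compound", "group")

#' Signed directed pathway graph
#'
#' A \code{PathwayGraph} holds the topology of one signalling pathway: gene,
#' compound and group nodes connected by signed (activation/inhibition)
#' directed edges. After preprocessing with \code{\link{breakCycles}} and
#' \code{\link{assignRoles}} the edge set is acyclic, \code{inputNodes} are
#' the in-degree-0 nodes where signal propagation starts, and
#' \code{sinkNodes} are the out-degree-0 terminal nodes whose propagated
#' signal is the branch activity readout.
#'
#' @slot pathwayId single identifier string.
#' @slot name display name.
#' @slot nodes data.frame with columns \code{node_id}, \code{label},
#'   \code{node_class} (one of gene/compound/group) and a list column
#'   \code{member_genes} of gene symbols mapped to each node.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (activation or inhibition).
#' @slot inputNodes,sinkNodes character vectors of node ids; empty until
#'   \code{\link{assignRoles}} has been run.
#' @slot removedEdges data.frame of edges removed by
#'   \code{\link{breakCycles}} (audit trail).
#'
#' @seealso \code{\link{parseKGML}}, \code{\link{readPathwayTables}},
#'   \code{\link{preprocessPathway}}
#' @export
setClass("PathwayGraph",
  representation(
    pathwayId    = "character",
    name         = "character",
    nodes        = "data.frame",
    edges        = "data.frame",
    inputNodes   = "character",
    sinkNodes    = "character",
    removedEdges = "data.frame"
  ),
  prototype(
    pathwayId = NA_character_, name = NA_character_,
    inputNodes = character(), sinkNodes = character()
  )
)

setValidity("PathwayGraph", function(object) {
  msgs <- character()
  nd <- object@nodes
  ed <- object@edges
  need_nd <- c("node_id", "label", "node_class", "member_genes")
  if (!all(need_nd %in% names(nd)))
    return(paste("nodes must have columns:", paste(need_nd, collapse = ", ")))
  if (anyDuplicated(nd$node_id))
    msgs <- c(msgs, sprintf("duplicate node_id: %s",
      paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", ")))
  if (!all(nd$node_class %in% VALID_NODE_CLASSES))
    msgs <- c(msgs, "node_class must be one of gene/compound/group")
  need_ed <- c("source", "target", "sign")
  if (!all(need_ed %in% names(ed)))
    return(paste("edges must have columns:", paste(need_ed, collapse = ", ")))
  if (nrow(ed)) {
    bad <- setdiff(unique(c(ed$source, ed$target)), nd$node_id)
    if (length(bad))
      msgs <- c(msgs, sprintf("edges reference undefined nodes: %s",
        paste(bad, collapse = ", ")))
    if (!all(ed$sign %in% VALID_EDGE_SIGNS))
      msgs <- c(msgs, "edge sign must be activation or inhibition")
  }
  bad_roles <- setdiff(c(object@inputNodes, object@sinkNodes), nd$node_id)
  if (length(bad_roles))
    msgs <- c(msgs, sprintf("role annotation references undefined nodes: %s",
      paste(bad_roles, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# internal constructor; normalizes column types and the member_genes list
newPathwayGraph <- function(pathwayId, name, nodes, edges,
                            inputNodes = character(),
                            sinkNodes = character(),
                            removedEdges = emptyEdgeFrame()) {
  nodes$node_id <- as.character(nodes$node_id)
  nodes$label <- as.character(nodes$label)
  nodes$node_class <- as.character(nodes$node_class)
  if (!is.list(nodes$member_genes))
    nodes$member_genes <- as.list(nodes$member_genes)
  nodes$member_genes <- lapply(nodes$member_genes, function(g) {
    g <- as.character(g)
    g[nzchar(g)]
  })
  rownames(nodes) <- NULL
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cl in c("source", "target", "sign"))
    edges[[cl]] <- as.character(edges[[cl]])
  rownames(edges) <- NULL
  new("PathwayGraph",
      pathwayId = as.character(pathwayId), name = as.character(name),
      nodes = nodes, edges = edges,
      inputNodes = inputNodes, sinkNodes = sinkNodes,
      removedEdges = removedEdges)
}

emptyEdgeFrame <- function() {
  data.frame(source = character(), target = character(),
             sign = character(), stringsAsFactors = FALSE)
}

#' Spot-level expression container
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{counts} assay is a
#' genes x spots (sparse-capable) non-negative integer matrix, and
#' \code{colData} carries per-spot metadata including planar coordinates
#' (\code{coord_y}, \code{coord_x}, full-resolution pixel convention) and the
#' \code{in_tissue} flag.
#'
#' @seealso \code{\link{readVisium}}, \code{\link{spotCoords}}
#' @export
setClass("SpotExpression", contains = "SummarizedExperiment")

setValidity("SpotExpression", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cd <- colData(object)
  need <- c("coord_y", "coord_x", "in_tissue")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate spot barcodes")
  if (!all(is.finite(cd$coord_y)) || !all(is.finite(cd$coord_x)))
    msgs <- c(msgs, "spot coordinates must be finite")
  m <- assay(object, "counts")
  if (min0(m) < 0)
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# min of a (possibly sparse) matrix, 0 for an empty one
min0 <- function(m) if (length(m)) min(m) else 0

#' Branch-level pathway activity container
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{activity} assay is a
#' sinks x spots matrix of strictly positive pathway signal flow values (1 =
#' neutral), with \code{rowData} columns \code{pathway_id}, \code{node_id}
#' and \code{label} identifying each sink (terminal) node.
#'
#' @seealso \code{\link{runPSF}}, \code{\link{sinkIndex}}
#' @export
setClass("ActivityMatrix", contains = "SummarizedExperiment")

setValidity("ActivityMatrix", function(object) {
  msgs <- character()
  if (!"activity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'activity' is required")
  rd <- rowData(object)
  need <- c("pathway_id", "node_id", "label")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns:", paste(need, collapse = ", ")))
  key <- paste(rd$pathway_id, rd$node_id, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicated (pathway_id, node_id) sink key")
  a <- assay(object, "activity")
  if (length(a) && (any(!is.finite(a)) || any(a <= 0)))
    msgs <- c(msgs, "activity values must be finite and strictly positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
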