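#' @rdname PathwayGraph-accessors
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("pathwayName", function(x) standardGeneric("pathwayName"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("inputNodes", function(x) standardGeneric("inputNodes"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("sinkNodes", function(x) standardGeneric("sinkNodes"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("removedEdges", function(x) standardGeneric("removedEdges"))
#' @rdname PathwayGraph-accessors
#' @export
setGeneric("memberGenes", function(x) standardGeneric("memberGenes"))

#' Accessors for PathwayGraph objects
#'
#' @param x a \linkS4class{PathwayGraph}.
#' @return \code{pathwayId}, \code{pathwayName}: a string;
#'   \code{pathwayNodes}, \code{pathwayEdges}, \code{removedEdges}:
#'   data.frames; \code{inputNodes}, \code{sinkNodes}: character vectors of
#'   node ids; \code{memberGenes}: named list of gene symbols per node.
#' @name PathwayGraph-accessors
NULL

#' @rdname PathwayGraph-accessors
setMethod("pathwayId", "PathwayGraph", function(x) x@pathwayId)
#' @rdname PathwayGraph-accessors
setMethod("pathwayName", "PathwayGraph", function(x) x@name)
#' @rdname PathwayGraph-accessors
setMethod("pathwayNodes", "PathwayGraph", function(x) x@nodes)
#' @rdname PathwayGraph-accessors
setMethod("pathwayEdges", "PathwayGraph", function(x) x@edges)
#' @rdname PathwayGraph-accessors
setMethod("inputNodes", "PathwayGraph", function(x) x@inputNodes)
#' @rdname PathwayGraph-accessors
setMethod("sinkNodes", "PathwayGraph", function(x) x@sinkNodes)
#' @rdname PathwayGraph-accessors
setMethod("removedEdges", "PathwayGraph", function(x) x@removedEdges)
#' @rdname PathwayGraph-accessors
setMethod("memberGenes", "PathwayGraph", function(x) {
  stats::setNames(x@nodes$member_genes, x@nodes$node_id)
})

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph '%s' (%s)\n", object@pathwayId, object@name))
  cat(sprintf("  %d nodes, %d edges (%d activation, %d inhibition)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$sign == "activation"),
              sum(object@edges$sign == "inhibition")))
  if (length(object@inputNodes) || length(object@sinkNodes))
    cat(sprintf("  roles: %d input, %d sink nodes\n",
                length(object@inputNodes), length(object@sinkNodes)))
  else
    cat("  roles: not assigned (run preprocessPathway())\n")
  if (nrow(object@removedEdges))
    cat(sprintf("  %d edges removed during cycle breaking\n",
                nrow(object@removedEdges)))
  invisible(NULL)
})

#' @rdname spotCoords
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' Spot coordinates and tissue flag
#'
#' @param x a \linkS4class{SpotExpression}.
#' @return \code{spotCoords}: a spots x 2 numeric matrix with columns
#'   \code{y}, \code{x} (full-resolution pixel convention, Euclidean
#'   distances); \code{inTissue}: a named logical vector.
#' @name spotCoords
#' @export
setMethod("spotCoords", "SpotExpression", function(x) {
  cd <- colData(x)
  m <- cbind(y = cd$coord_y, x = cd$coord_x)
  rownames(m) <- colnames(x)
  m
})

#' @rdname spotCoords
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))

#' @rdname spotCoords
setMethod("inTissue", "SpotExpression", function(x) {
  stats::setNames(colData(x)$in_tissue, colnames(x))
})

#' @rdname sinkIndex
#' @export
setGeneric("sinkIndex", function(x) standardGeneric("sinkIndex"))

#' Sink index of an ActivityMatrix
#'
#' @param x an \linkS4class{ActivityMatrix}.
#' @return data.frame with one row per sink: \code{pathway_id},
#'   \code{node_id}, \code{label}.
#' @name sinkIndex
#' @export
setMethod("sinkIndex", "ActivityMatrix", function(x) {
  as.data.frame(rowData(x)[, c("pathway_id", "node_id", "label")])
})
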