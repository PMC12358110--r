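# signals are clamped to this range during propagation to keep long
# multiplicative chains finite; clamping events are counted and reported
PSF_CLAMP <- c(1e-12, 1e12)

#' Map gene fold-changes onto pathway nodes
#'
#' A gene node's value is the aggregate (default: arithmetic mean) of the
#' fold-changes of its measured member genes. Nodes with no measured member
#' gene, compound nodes and group placeholders get the neutral value 1, so
#' they pass signal through without amplifying or damping it.
#'
#' @param fc genes x spots strictly positive fold-change matrix
#'   (\code{\link{computeFoldChange}}).
#' @param graph a \linkS4class{PathwayGraph}.
#' @param aggregator "mean", "median" or "geomean".
#' @return nodes x spots matrix of node values (rows ordered as
#'   \code{pathwayNodes(graph)}).
#' @export
mapNodeValues <- function(fc, graph, aggregator = c("mean", "median", "geomean")) {
  stopifnot(is(graph, "PathwayGraph"))
  aggregator <- match.arg(aggregator)
  fc <- as.matrix(fc)
  if (any(fc <= 0)) stop("fold-changes must be strictly positive")
  agg <- switch(aggregator,
    mean = colMeans,
    median = function(m) apply(m, 2, stats::median),
    geomean = function(m) exp(colMeans(log(m))))
  nd <- graph@nodes
  vals <- matrix(1, nrow(nd), ncol(fc),
                 dimnames = list(nd$node_id, colnames(fc)))
  for (i in seq_len(nrow(nd))) {
    if (nd$node_class[i] != "gene") next
    members <- intersect(nd$member_genes[[i]], rownames(fc))
    if (!length(members)) next
    vals[i, ] <- agg(fc[members, , drop = FALSE])
  }
  vals
}

#' Propagate node values through a pathway
#'
#' Pathway signal flow: nodes are processed in topological order. An input
#' node's signal is its own value; any other node's signal is its own value
#' times the product over incoming edges of the parent contribution --- the
#' parent signal for an activation edge, its reciprocal for an inhibition
#' edge. Signals are clamped to [1e-12, 1e12]; the number of clamped entries
#' is attached as attribute \code{"n_clamped"}.
#'
#' @param graph an acyclic, role-annotated \linkS4class{PathwayGraph}.
#' @param values nodes x spots matrix from \code{\link{mapNodeValues}}
#'   (every graph node must have a row).
#' @return nodes x spots matrix of strictly positive signals.
#' @export
propagateSignal <- function(graph, values) {
  stopifnot(is(graph, "PathwayGraph"))
  values <- as.matrix(values)
  ids <- graph@nodes$node_id
  missing <- setdiff(ids, rownames(values))
  if (length(missing))
    stop("missing node value(s): ", paste(missing, collapse = ", "))
  ord <- topologicalOrder(graph)   # errors on a cycle
  ed <- graph@edges
  in_edges <- split(seq_len(nrow(ed)), factor(ed$target, levels = ids))
  signals <- values[ids, , drop = FALSE]
  n_clamped <- 0L
  for (v in ord) {
    eix <- in_edges[[v]]
    if (!length(eix)) next       # input node: signal = own value
    contrib <- rep(1, ncol(values))
    for (e in eix) {
      p <- signals[ed$source[e], ]
      contrib <- contrib * if (ed$sign[e] == "activation") p else 1 / p
    }
    s <- values[v, ] * contrib
    out <- s < PSF_CLAMP[1] | s > PSF_CLAMP[2]
    if (any(out)) {
      n_clamped <- n_clamped + sum(out)
      s <- pmin(pmax(s, PSF_CLAMP[1]), PSF_CLAMP[2])
    }
    signals[v, ] <- s
  }
  attr(signals, "n_clamped") <- n_clamped
  signals
}

#' Extract sink-node activities for one pathway
#'
#' @param graph a role-annotated \linkS4class{PathwayGraph}.
#' @param signals nodes x spots matrix from \code{\link{propagateSignal}}.
#' @return sinks x spots matrix; rownames are sink node ids, with a
#'   \code{"sink_index"} attribute carrying (pathway_id, node_id, label).
#' @export
sinkActivities <- function(graph, signals) {
  stopifnot(is(graph, "PathwayGraph"))
  sinks <- graph@sinkNodes
  if (!length(sinks))
    stop(sprintf("pathway '%s' has no sink nodes (unanalyzable); was assignRoles() run?",
                 graph@pathwayId))
  sinks <- sort(sinks)
  a <- signals[sinks, , drop = FALSE]
  labels <- graph@nodes$label[match(sinks, graph@nodes$node_id)]
  attr(a, "sink_index") <- data.frame(
    pathway_id = graph@pathwayId, node_id = sinks, label = labels,
    stringsAsFactors = FALSE)
  a
}

#' Run pathway signal flow over a pathway collection
#'
#' Maps fold-changes onto nodes, propagates them, and concatenates the sink
#' activities of every pathway into one \linkS4class{ActivityMatrix}.
#' Pathways are processed independently, so results do not depend on
#' processing order.
#'
#' @param fc genes x spots strictly positive fold-change matrix.
#' @param pathways list of preprocessed \linkS4class{PathwayGraph} objects.
#' @param aggregator node-value aggregator, see \code{\link{mapNodeValues}}.
#' @return an \linkS4class{ActivityMatrix} (sinks x spots, assay
#'   \code{"activity"}).
#' @export
runPSF <- function(fc, pathways, aggregator = "mean") {
  if (is(pathways, "PathwayGraph")) pathways <- list(pathways)
  if (!length(pathways)) stop("at least one pathway is required")
  fc <- as.matrix(fc)
  blocks <- lapply(pathways, function(g) {
    vals <- mapNodeValues(fc, g, aggregator)
    sig <- propagateSignal(g, vals)
    sinkActivities(g, sig)
  })
  idx <- do.call(rbind, lapply(blocks, attr, "sink_index"))
  key <- paste(idx$pathway_id, idx$node_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (pathway_id, node_id) sink key: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  a <- do.call(rbind, lapply(blocks, function(b) { attr(b, "sink_index") <- NULL; b }))
  rownames(a) <- paste(idx$pathway_id, idx$node_id, sep = ":")
  se <- SummarizedExperiment(
    assays = list(activity = a),
    rowData = S4Vectors::DataFrame(idx, row.names = rownames(a)))
  methods::new("ActivityMatrix", se)
}

#' Write an ActivityMatrix as TSV
#'
#' Writes the activity table (sinks x spots) and a sink-index sidecar.
#'
#' @param activity an \linkS4class{ActivityMatrix}.
#' @param path output TSV path; the sidecar is written next to it with
#'   suffix \code{.sinks.tsv}.
#' @return \code{path}, invisibly.
#' @export
writeActivityMatrix <- function(activity, path) {
  stopifnot(is(activity, "ActivityMatrix"))
  a <- assay(activity, "activity")
  utils::write.table(data.frame(sink = rownames(a), a, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sinkIndex(activity),
                     sub("\\.tsv$", ".sinks.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
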