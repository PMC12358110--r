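#' Read a pathway from the native table format
#'
#' The native format is two TSVs plus a JSON metadata sidecar:
#' \code{nodes.tsv} with columns \code{node_id}, \code{member_genes}
#' (semicolon-joined, possibly empty) and \code{node_class}; \code{edges.tsv}
#' with columns \code{source}, \code{target}, \code{sign}; and
#' \code{pathway.json} with \code{pathway_id} and \code{name}. Round-trips
#' with \code{\link{writePathwayTables}}.
#'
#' @param dir directory containing \code{nodes.tsv}, \code{edges.tsv} and
#'   (optionally) \code{pathway.json}.
#' @return an unpreprocessed \linkS4class{PathwayGraph}.
#' @export
readPathwayTables <- function(dir) {
  nodes_path <- file.path(dir, "nodes.tsv")
  edges_path <- file.path(dir, "edges.tsv")
  if (!file.exists(nodes_path) || !file.exists(edges_path))
    stop("expected nodes.tsv and edges.tsv in ", dir)
  nd <- utils::read.delim(nodes_path, colClasses = "character")
  ed <- utils::read.delim(edges_path, colClasses = "character")
  if (!nrow(ed)) ed <- emptyEdgeFrame()
  if (anyDuplicated(nd$node_id))
    stop("duplicate node_id in ", nodes_path, ": ",
         paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", "))
  bad_sign <- setdiff(unique(ed$sign), VALID_EDGE_SIGNS)
  if (length(bad_sign))
    stop("unknown sign token(s) in ", edges_path, ": ",
         paste(bad_sign, collapse = ", "),
         " (expected activation or inhibition)")
  meta_path <- file.path(dir, "pathway.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(pathway_id = basename(dir), name = basename(dir))
  if (is.null(nd$label)) nd$label <- nd$node_id
  nd$member_genes[is.na(nd$member_genes)] <- ""
  nd$member_genes <- lapply(strsplit(nd$member_genes, ";", fixed = TRUE),
                            function(g) g[nzchar(g)])
  g <- newPathwayGraph(meta$pathway_id, meta$name,
                       nd[, c("node_id", "label", "node_class", "member_genes")],
                       ed[, c("source", "target", "sign")])
  validObject(g)
  g
}

#' Write a pathway in the native table format
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePathwayTables <- function(graph, dir) {
  stopifnot(is(graph, "PathwayGraph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- graph@nodes
  out_nd <- data.frame(
    node_id = nd$node_id,
    label = nd$label,
    member_genes = vapply(nd$member_genes, paste, character(1), collapse = ";"),
    node_class = nd$node_class,
    stringsAsFactors = FALSE)
  utils::write.table(out_nd, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph@edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(pathway_id = graph@pathwayId, name = graph@name),
                       file.path(dir, "pathway.json"), auto_unbox = TRUE)
  invisible(dir)
}
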