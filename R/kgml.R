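KGML_ACTIVATING <- c("activation", "expression")
KGML_INHIBITING <- c("inhibition", "repression")

#' Parse a KEGG KGML pathway file
#'
#' Reads the KEGG XML dialect: \code{entry} elements of type gene or
#' compound become nodes (the entry \code{name} attribute is tokenised into
#' member gene identifiers, with database prefixes such as \code{hsa:}
#' stripped; the graphics name supplies the display label), and
#' \code{relation} elements become signed edges. Subtypes named activation
#' or expression map to activation; inhibition or repression map to
#' inhibition (so e.g. a phosphorylation relation also carrying an
#' activation subtype is kept as activation); relations carrying neither are
#' dropped with a warning. Group entries are expanded: every edge incident
#' to a group is duplicated onto each of its component entries and the group
#' placeholder is removed. Input/sink roles are not assigned; run
#' \code{\link{preprocessPathway}} next.
#'
#' @param path path to a KGML XML file.
#' @return an unpreprocessed \linkS4class{PathwayGraph}.
#' @export
parseKGML <- function(path) {
  doc <- xml2::read_xml(path)   # malformed XML errors with line info
  root <- doc
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- basename(path)
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, ".//entry")
  ent_id <- xml2::xml_attr(entries, "id")
  ent_type <- xml2::xml_attr(entries, "type")
  ent_name <- xml2::xml_attr(entries, "name")
  all_ids <- ent_id

  strip_db <- function(tok) sub("^[A-Za-z.]+:", "", tok)
  labels <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    lab <- if (inherits(g, "xml_node")) xml2::xml_attr(g, "name") else NA
    if (is.na(lab) || !nzchar(lab)) NA_character_
    else trimws(strsplit(lab, ",", fixed = TRUE)[[1]][1])
  }, character(1))

  keep <- ent_type %in% c("gene", "compound", "group")
  group_ids <- ent_id[ent_type == "group"]
  components <- lapply(entries, function(e)
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id"))
  names(components) <- ent_id

  nodes <- data.frame(
    node_id = ent_id[keep],
    label = ifelse(is.na(labels[keep]), ent_name[keep], labels[keep]),
    node_class = ent_type[keep],
    stringsAsFactors = FALSE)
  nodes$member_genes <- lapply(which(keep), function(i) {
    if (ent_type[i] != "gene") return(character(0))
    strip_db(strsplit(trimws(ent_name[i]), "\\s+")[[1]])
  })

  rels <- xml2::xml_find_all(doc, ".//relation")
  src <- xml2::xml_attr(rels, "entry1")
  tgt <- xml2::xml_attr(rels, "entry2")
  undef <- setdiff(c(src, tgt), all_ids)
  if (length(undef))
    stop(sprintf("relation(s) reference undefined entry id(s): %s",
                 paste(sort(unique(undef)), collapse = ", ")))

  subtype_names <- lapply(rels, function(r)
    xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name"))
  sign <- vapply(subtype_names, function(s) {
    if (any(s %in% KGML_ACTIVATING)) "activation"
    else if (any(s %in% KGML_INHIBITING)) "inhibition"
    else NA_character_
  }, character(1))

  node_ids <- nodes$node_id
  usable <- src %in% node_ids & tgt %in% node_ids
  n_unmappable <- sum(!is.na(src) & is.na(sign) & usable)
  if (n_unmappable)
    warning(sprintf("%d relation(s) dropped: subtype not mappable to activation/inhibition",
                    n_unmappable))
  n_skipped <- sum(!usable)
  if (n_skipped)
    warning(sprintf("%d relation(s) dropped: endpoint entry of unsupported type",
                    n_skipped))
  ok <- usable & !is.na(sign)
  edges <- data.frame(source = src[ok], target = tgt[ok], sign = sign[ok],
                      stringsAsFactors = FALSE)

  g <- newPathwayGraph(pid, pname, nodes, edges)
  expandGroups(g, group_ids, components)
}

# replace each group node by its components, duplicating incident edges
expandGroups <- function(graph, group_ids, components) {
  if (!length(group_ids)) return(graph)
  ed <- graph@edges
  for (gid in group_ids) {
    comp <- components[[gid]]
    comp <- intersect(comp, graph@nodes$node_id)
    if (!length(comp)) {         # empty group: just drop it and its edges
      ed <- ed[ed$source != gid & ed$target != gid, , drop = FALSE]
    } else {
      expand_rows <- function(df, col) {
        hit <- df[[col]] == gid
        if (!any(hit)) return(df)
        dup <- df[rep(which(hit), each = length(comp)), , drop = FALSE]
        dup[[col]] <- rep(comp, times = sum(hit))
        rbind(df[!hit, , drop = FALSE], dup)
      }
      ed <- expand_rows(expand_rows(ed, "source"), "target")
    }
  }
  keep <- !(graph@nodes$node_id %in% group_ids)
  graph@nodes <- graph@nodes[keep, , drop = FALSE]
  rownames(graph@nodes) <- NULL
  ed <- unique(ed)   # group expansion can duplicate rows; self-loops are left
                     # for breakCycles() to record
  rownames(ed) <- NULL
  graph@edges <- ed
  validObject(graph)
  graph
}
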