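# Independent oracles used across the suite. These deliberately avoid the
# package's own traversal code paths.

# memo-free recursive evaluation of the propagation rule at one node for
# one spot: signal(v) = value(v) * prod over incoming edges of parent
# signal (activation) or its reciprocal (inhibition)
oracle_signal <- function(graph, values_vec, node) {
  ed <- pathwayEdges(graph)
  ix <- which(ed$target == node)
  s <- values_vec[[node]]
  for (e in ix) {
    p <- oracle_signal(graph, values_vec, ed$source[e])
    s <- s * if (ed$sign[e] == "activation") p else 1 / p
  }
  s
}

# brute-force cycle detection via powers of the adjacency matrix:
# a cycle exists iff some A^k (k <= n) has a positive diagonal entry
oracle_has_cycle <- function(graph) {
  ids <- pathwayNodes(graph)$node_id
  n <- length(ids)
  ed <- pathwayEdges(graph)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(ed))) A[ed$source[i], ed$target[i]] <- 1
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- P %*% A
    if (any(diag(P) > 0)) return(TRUE)
  }
  FALSE
}

# exhaustive two-sided rank-sum p-value: enumerate all C(n+m, n) group
# assignments of the pooled values and count rank sums at least as extreme
oracle_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# random pathway-like graph (possibly cyclic) for property sweeps
random_digraph <- function(n_nodes, p_edge, p_inhib = 0.3, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    keep <- runif(nrow(pairs)) < p_edge
    edges <- pairs[keep, ]
    edges$sign <- ifelse(runif(nrow(edges)) < p_inhib,
                         "inhibition", "activation")
    nodes <- data.frame(node_id = ids, label = ids, node_class = "gene",
                        stringsAsFactors = FALSE)
    nodes$member_genes <- lapply(ids, function(i) paste0(i, "_G1"))
    SpatialPSF:::newPathwayGraph("RND", "random", nodes, edges)
  })
}

# minimal KGML document writer for parser tests
write_kgml <- function(path, entries, relations) {
  ent <- vapply(entries, function(e) {
    comp <- if (!is.null(e$components))
      paste(sprintf('<component id="%s"/>', e$components), collapse = "")
    else ""
    sprintf('<entry id="%s" name="%s" type="%s"><graphics name="%s"/>%s</entry>',
            e$id, e$name, e$type, if (is.null(e$label)) e$name else e$label,
            comp)
  }, character(1))
  rel <- vapply(relations, function(r) {
    sub <- paste(sprintf('<subtype name="%s" value=""/>', r$subtypes),
                 collapse = "")
    sprintf('<relation entry1="%s" entry2="%s" type="PPrel">%s</relation>',
            r$from, r$to, sub)
  }, character(1))
  writeLines(c('<?xml version="1.0"?>',
               '<pathway name="path:test01" org="hsa" title="Test pathway">',
               ent, rel, '</pathway>'), path)
  path
}

# small helper: preprocessed activation chain with explicit members
chain_graph <- function(id = "CH", nodes = c("A", "B", "C"),
                        signs = rep("activation", length(nodes) - 1),
                        members = NULL) {
  if (is.null(members))
    members <- setNames(as.list(paste0(nodes, "_G1")), nodes)
  nd <- data.frame(node_id = nodes, label = nodes, node_class = "gene",
                   stringsAsFactors = FALSE)
  nd$member_genes <- lapply(nodes, function(x) members[[x]])
  k <- length(nodes)
  ed <- if (k > 1)
    data.frame(source = nodes[-k], target = nodes[-1], sign = signs,
               stringsAsFactors = FALSE)
  else SpatialPSF:::emptyEdgeFrame()
  preprocessPathway(SpatialPSF:::newPathwayGraph(id, id, nd, ed))
}
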