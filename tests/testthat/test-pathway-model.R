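test_that("KGML parsing maps entries and relations to signed nodes/edges", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_kgml(f,
    entries = list(list(id = "1", name = "hsa:111", type = "gene"),
                   list(id = "2", name = "hsa:222", type = "gene")),
    relations = list(list(from = "1", to = "2", subtypes = "activation")))
  g <- parseKGML(f)
  expect_s4_class(g, "PathwayGraph")
  expect_equal(nrow(pathwayNodes(g)), 2)
  expect_equal(pathwayEdges(g)$sign, "activation")
  expect_equal(pathwayEdges(g)$source, "1")

  # multi-gene entry name -> member_genes of length 2, prefixes stripped
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_kgml(f2,
    entries = list(list(id = "1", name = "hsa:111 hsa:222", type = "gene")),
    relations = list())
  g2 <- parseKGML(f2)
  expect_equal(memberGenes(g2)[["1"]], c("111", "222"))
})

test_that("KGML referential integrity and subtype mapping are enforced", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_kgml(f,
    entries = list(list(id = "1", name = "hsa:111", type = "gene")),
    relations = list(list(from = "1", to = "99", subtypes = "activation")))
  expect_error(parseKGML(f), "undefined entry")

  # inhibition-like and unmappable subtypes
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_kgml(f2,
    entries = list(list(id = "1", name = "hsa:1", type = "gene"),
                   list(id = "2", name = "hsa:2", type = "gene"),
                   list(id = "3", name = "hsa:3", type = "gene")),
    relations = list(
      list(from = "1", to = "2", subtypes = "repression"),
      list(from = "1", to = "2", subtypes = c("phosphorylation", "activation")),
      list(from = "2", to = "3", subtypes = "binding/association")))
  expect_warning(g2 <- parseKGML(f2), "not mappable")
  expect_setequal(pathwayEdges(g2)$sign, c("inhibition", "activation"))
  expect_equal(nrow(pathwayEdges(g2)), 2)
})

test_that("KGML group entries are expanded onto their components", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_kgml(f,
    entries = list(list(id = "1", name = "hsa:1", type = "gene"),
                   list(id = "2", name = "hsa:2", type = "gene"),
                   list(id = "3", name = "hsa:3", type = "gene"),
                   list(id = "10", name = "undefined", type = "group",
                        components = c("1", "2"))),
    relations = list(list(from = "10", to = "3", subtypes = "activation")))
  g <- parseKGML(f)
  expect_setequal(pathwayNodes(g)$node_id, c("1", "2", "3"))
  ed <- pathwayEdges(g)
  expect_setequal(paste(ed$source, ed$target), c("1 3", "2 3"))
})

test_that("native table format round-trips and validates", {
  g <- chain_graph("RT", c("A", "B", "C", "D"),
                   signs = c("activation", "inhibition", "activation"))
  d <- withr::local_tempdir()
  writePathwayTables(g, d)
  g2 <- readPathwayTables(d)
  expect_equal(pathwayId(g2), "RT")
  expect_equal(pathwayNodes(g2)$node_id, pathwayNodes(g)$node_id)
  expect_equal(pathwayNodes(g2)$member_genes, pathwayNodes(g)$member_genes)
  expect_equal(pathwayEdges(g2), pathwayEdges(g))

  # sign validation
  ed <- read.delim(file.path(d, "edges.tsv"))
  ed$sign[2] <- "maybe"
  write.table(ed, file.path(d, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readPathwayTables(d), "maybe")

  # duplicate node ids
  d2 <- withr::local_tempdir()
  writePathwayTables(g, d2)
  nd <- read.delim(file.path(d2, "nodes.tsv"))
  nd <- rbind(nd, nd[1, ])
  write.table(nd, file.path(d2, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readPathwayTables(d2), "duplicate")
})

test_that("an edge list builds the expected graph, including degenerate cases", {
  d <- withr::local_tempdir()
  writeLines(c("node_id\tmember_genes\tnode_class",
               "A\tg1\tgene", "B\tg2;g3\tgene", "C\t\tgene", "D\tg4\tgene"),
             file.path(d, "nodes.tsv"))
  writeLines(c("source\ttarget\tsign",
               "A\tB\tactivation", "B\tC\tactivation", "B\tD\tinhibition"),
             file.path(d, "edges.tsv"))
  g <- readPathwayTables(d)
  expect_equal(nrow(pathwayNodes(g)), 4)
  expect_equal(nrow(pathwayEdges(g)), 3)
  expect_equal(memberGenes(g)[["B"]], c("g2", "g3"))
  expect_equal(memberGenes(g)[["C"]], character(0))

  # empty edge list with one node
  d2 <- withr::local_tempdir()
  writeLines(c("node_id\tmember_genes\tnode_class", "X\tg1\tgene"),
             file.path(d2, "nodes.tsv"))
  writeLines("source\ttarget\tsign", file.path(d2, "edges.tsv"))
  g2 <- readPathwayTables(d2)
  expect_equal(nrow(pathwayNodes(g2)), 1)
  expect_equal(nrow(pathwayEdges(g2)), 0)
})

test_that("breakCycles leaves acyclic graphs untouched and breaks minimal cycles", {
  diamond <- SpatialPSF:::newPathwayGraph("D", "diamond",
    data.frame(node_id = c("A", "B", "C", "D"), label = c("A", "B", "C", "D"),
               node_class = "gene",
               member_genes = I(as.list(paste0(c("A","B","C","D"), "g"))),
               stringsAsFactors = FALSE),
    data.frame(source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
               sign = "activation", stringsAsFactors = FALSE))
  out <- breakCycles(diamond)
  expect_equal(nrow(removedEdges(out)), 0)
  expect_equal(pathwayEdges(out), pathwayEdges(diamond))

  two_cycle <- SpatialPSF:::newPathwayGraph("C2", "cycle",
    data.frame(node_id = c("A", "B"), label = c("A", "B"), node_class = "gene",
               member_genes = I(list("Ag", "Bg")), stringsAsFactors = FALSE),
    data.frame(source = c("A", "B"), target = c("B", "A"),
               sign = "activation", stringsAsFactors = FALSE))
  out2 <- breakCycles(two_cycle)
  expect_equal(nrow(removedEdges(out2)), 1)
  expect_true(isAcyclic(out2))
  expect_false(oracle_has_cycle(out2))
})

test_that("breakCycles is verified acyclic by the adjacency-power oracle on random graphs", {
  removed_when_acyclic <- integer(0)
  for (seed in 1:40) {
    g <- random_digraph(sample(4:12, 1), p_edge = 0.25, seed = seed)
    had_cycle <- oracle_has_cycle(g)
    out <- breakCycles(g)
    expect_false(oracle_has_cycle(out), info = paste("seed", seed))
    if (!had_cycle) removed_when_acyclic <-
        c(removed_when_acyclic, nrow(removedEdges(out)))
    # determinism
    out2 <- breakCycles(g)
    expect_identical(pathwayEdges(out), pathwayEdges(out2))
  }
  expect_true(all(removed_when_acyclic == 0))
})

test_that("roles are the degree-zero nodes of the preprocessed edge set", {
  g <- chain_graph("CH", c("A", "B", "C"))
  expect_equal(inputNodes(g), "A")
  expect_equal(sinkNodes(g), "C")

  iso <- chain_graph("ISO", "X")
  expect_equal(inputNodes(iso), "X")
  expect_equal(sinkNodes(iso), "X")

  diamond <- chain_graph("D2", c("A", "B"))   # start from chain, add diamond edges
  nd <- data.frame(node_id = c("A", "B", "C", "D"),
                   label = c("A", "B", "C", "D"), node_class = "gene",
                   stringsAsFactors = FALSE)
  nd$member_genes <- as.list(paste0(nd$node_id, "g"))
  ed <- data.frame(source = c("A", "A", "B", "C"),
                   target = c("B", "C", "D", "D"),
                   sign = "activation", stringsAsFactors = FALSE)
  g2 <- assignRoles(SpatialPSF:::newPathwayGraph("D3", "d", nd, ed))
  expect_equal(inputNodes(g2), "A")
  expect_equal(sinkNodes(g2), "D")

  empty <- SpatialPSF:::newPathwayGraph("E", "empty",
    data.frame(node_id = character(), label = character(),
               node_class = character(),
               member_genes = I(list()), stringsAsFactors = FALSE),
    SpatialPSF:::emptyEdgeFrame())
  expect_error(assignRoles(empty), "zero nodes")
})

test_that("roles recomputed from scratch equal stored roles after preprocessing", {
  for (seed in 1:20) {
    g <- preprocessPathway(random_digraph(10, 0.25, seed = seed))
    ids <- pathwayNodes(g)$node_id
    ed <- pathwayEdges(g)
    expect_setequal(inputNodes(g), ids[!ids %in% ed$target])
    expect_setequal(sinkNodes(g), ids[!ids %in% ed$source])
  }
})
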