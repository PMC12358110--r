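test_that("hex lattice adjacency recovers 6 interior / 2-3 corner neighbours", {
  l <- SpatialPSF:::hexLattice(6)
  co <- cbind(y = l$y, x = l$x)
  rownames(co) <- l$spot_id
  adj <- spotAdjacency(co)
  counts <- lengths(adj$neighbors)
  # interior spot: row 3, col 3
  interior <- l$spot_id[l$array_row == 3 & l$array_col == 3]
  expect_equal(counts[[interior]], 6)
  corner <- l$spot_id[l$array_row == 0 & l$array_col == 0]
  expect_true(counts[[corner]] %in% 2:3)
  # symmetry and self-exclusion
  for (s in names(adj$neighbors)) {
    expect_false(s %in% adj$neighbors[[s]])
    for (t in adj$neighbors[[s]])
      expect_true(s %in% adj$neighbors[[t]])
  }
})

test_that("adjacency equals brute-force distance thresholding on jittered points", {
  set.seed(14)
  l <- SpatialPSF:::hexLattice(5)
  co <- cbind(y = l$y + runif(25, -0.05, 0.05),
              x = l$x + runif(25, -0.05, 0.05))
  rownames(co) <- l$spot_id
  adj <- spotAdjacency(co, scaleFactor = 1.3)
  d <- as.matrix(dist(co)); diag(d) <- Inf
  thr <- 1.3 * min(d)
  for (i in seq_len(nrow(co)))
    expect_setequal(adj$neighbors[[i]], rownames(co)[d[i, ] <= thr])
  expect_error(spotAdjacency(rbind(co, co[1, , drop = FALSE])), "duplicate")
  expect_error(spotAdjacency(co[1, , drop = FALSE]), "at least 2")
})

test_that("half-plane clusters yield facing border groups with cores behind them", {
  l <- SpatialPSF:::hexLattice(8)
  co <- cbind(y = l$y, x = l$x)
  rownames(co) <- l$spot_id
  labels <- setNames(as.integer(l$array_col >= 4), l$spot_id)
  adj <- spotAdjacency(co)
  groups <- classifyCoreBorder(labels, adj, minGroup = 2)
  b0 <- groups[groups$cluster == 0 & groups$role == "border", ]
  expect_true(all(b0$adjacent_cluster == 1))
  # border spots of cluster 0 hug the interface columns
  expect_true(all(l$array_col[match(b0$spot_id, l$spot_id)] %in% 3:4))
  core0 <- groups[groups$cluster == 0 & groups$role == "core", ]
  expect_true(all(l$array_col[match(core0$spot_id, l$spot_id)] <= 2))
  # every spot is core xor border within its cluster
  expect_false(any(groups$spot_id[groups$role == "core"] %in%
                   groups$spot_id[groups$role == "border"]))
  expect_setequal(groups$spot_id, l$spot_id)
})

test_that("three-region pinwheel gives the centre cluster two border groups", {
  l <- SpatialPSF:::hexLattice(9)
  co <- cbind(y = l$y, x = l$x)
  rownames(co) <- l$spot_id
  labels <- setNames(ifelse(l$array_col < 3, 0L,
                            ifelse(l$array_col < 6, 1L, 2L)), l$spot_id)
  adj <- spotAdjacency(co)
  groups <- classifyCoreBorder(labels, adj, minGroup = 2)
  centre_borders <- unique(groups$adjacent_cluster[
    groups$cluster == 1 & groups$role == "border"])
  expect_setequal(centre_borders, c(0L, 2L))
  # hand-checked: a centre spot adjacent to cluster 0 sits in column 3
  b10 <- groups[groups$cluster == 1 & groups$adjacent_cluster %in% 0, ]
  expect_true(all(l$array_col[match(b10$spot_id, l$spot_id)] == 3))
})

test_that("tiny groups are dropped with a warning", {
  l <- SpatialPSF:::hexLattice(5)
  co <- cbind(y = l$y, x = l$x)
  rownames(co) <- l$spot_id
  labels <- setNames(rep(0L, 25), l$spot_id)
  labels[13] <- 1L      # singleton cluster
  adj <- spotAdjacency(co)
  expect_warning(groups <- classifyCoreBorder(labels, adj, minGroup = 2),
                 "dropped")
  expect_false(any(groups$cluster == 1))
})

test_that("group comparison equals the OLS closed form and lm reference", {
  set.seed(41)
  spots <- paste0("s", 1:60)
  la <- matrix(rnorm(5 * 60, 0, 0.4), 5, 60,
               dimnames = list(paste0("P1:k", 1:5), spots))
  la[2, 31:60] <- la[2, 31:60] + 0.8
  act <- 2^la
  ga <- spots[1:30]; gb <- spots[31:60]
  tab <- compareGroups(act, ga, gb)
  # coefficient = difference of group means, exactly
  for (i in 1:5)
    expect_equal(tab$coefficient[i], mean(la[i, gb]) - mean(la[i, ga]),
                 tolerance = 1e-12)
  # p equals the lm() t-test on the indicator
  fit <- summary(lm(la[2, ] ~ rep(0:1, each = 30)))
  expect_equal(tab$p[2], fit$coefficients[2, 4], tolerance = 1e-10)
  expect_true(tab$significant[2])
  expect_error(compareGroups(act, ga, c(gb, ga[1])), "overlap")
  expect_error(compareGroups(act, ga[1:2], gb), "at least 3")
})

test_that("null and planted-shift behaviour of the group comparison", {
  set.seed(51)
  spots <- paste0("s", 1:60)
  ga <- spots[1:30]; gb <- spots[31:60]
  rejections <- coef_hits <- logical(120)
  coefs <- numeric(120)
  for (r in 1:120) {
    la <- matrix(rnorm(4 * 60, 0, 0.3), 4, 60,
                 dimnames = list(paste0("P1:k", 1:4), spots))
    null_tab <- compareGroups(2^la, ga, gb)
    rejections[r] <- any(null_tab$significant)
    la[1, gb] <- la[1, gb] + 0.8
    tab <- compareGroups(2^la, ga, gb)
    coefs[r] <- tab$coefficient[1]
    coef_hits[r] <- tab$significant[1] &&
      tab$coefficient[1] > 0.6 && tab$coefficient[1] < 1.0
  }
  # family-wise null rejections stay modest (4 sinks, BH at 0.05)
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
  expect_gte(mean(coef_hits), 0.95)
  expect_equal(mean(coefs), 0.8, tolerance = 0.05)
})

test_that("ligand-receptor links require a shared gene and a significant reachable sink", {
  p1 <- chain_graph("P1", c("a", "b", "fasl_node"),
                    members = list(a = "A_G1", b = "B_G1",
                                   fasl_node = "FASLG"))
  p2 <- chain_graph("P2", c("rec", "mid", "out"),
                    members = list(rec = c("FASLG", "REC_G2"),
                                   mid = "MID_G1", out = "OUT_G1"))
  sigA <- data.frame(pathway_id = "P1", sink = "fasl_node")
  sigB <- data.frame(pathway_id = "P2", sink = "out")
  links <- ligandReceptorLinks(sigA, sigB, list(p1, p2))
  expect_equal(nrow(links), 1)
  expect_equal(links$gene, "FASLG")
  expect_equal(links$from_sink, "fasl_node")
  expect_equal(links$to_input, "rec")
  expect_equal(links$direction, "A->B")

  # no shared genes -> empty
  p2b <- chain_graph("P2", c("rec", "mid", "out"),
                     members = list(rec = "REC_G1", mid = "MID_G1",
                                    out = "OUT_G1"))
  expect_equal(nrow(ligandReceptorLinks(sigA, sigB, list(p1, p2b))), 0)

  # shared gene but no significant downstream sink -> no link
  sigB_none <- data.frame(pathway_id = character(), sink = character())
  expect_equal(nrow(ligandReceptorLinks(sigA, sigB_none, list(p1, p2))), 0)

  # link set invariant to pathway processing order
  links_rev <- ligandReceptorLinks(sigA, sigB, list(p2, p1))
  expect_equal(links, links_rev)
})
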