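test_that("NJ is exact in closed form for 2 and 3 taxa", {
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  tr2 <- nj_tree(dm2)
  expect_equal(sum(tr2$edge.length), 0.4)
  expect_equal(tr2$edge.length, c(0.2, 0.2))

  ids <- c("a", "b", "c")
  dm3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
                dimnames = list(ids, ids))
  tr3 <- nj_tree(dm3)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)

  dmbad <- dm3; dmbad[1, 2] <- NaN
  expect_error(nj_tree(dmbad), "non-finite")
})

test_that("NJ recovers random additive trees exactly, matching ape::nj", {
  set.seed(301)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    dm <- ape::cophenetic.phylo(tr)
    got <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(tr)), 0)
    patristic <- ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(patristic - dm)), 1e-9)
    # cross-check against the reference NJ implementation
    ref <- ape::nj(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(ref)), 0)
  }
})

test_that("midpoint rooting balances the deepest leaf paths", {
  tr2 <- midpoint_root(read_newick("(a:0.6,b:0.4);"))
  expect_equal(tr2$edge.length, c(0.5, 0.5))
  set.seed(311)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:10, 1))
    rooted <- midpoint_root(ape::unroot(tr))
    d <- ape::node.depth.edgelength(rooted)[seq_len(ape::Ntip(rooted))]
    root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
    sides <- lapply(root_children, function(v) {
      if (v <= ape::Ntip(rooted)) v
      else intersect(unlist(polswap:::.leaves_below(rooted)[v]),
                     seq_len(ape::Ntip(rooted)))
    })
    expect_equal(max(d[sides[[1]]]), max(d[sides[[2]]]), tolerance = 1e-9)
  }
})

test_that("ultrametrize balances subtrees with preserved topology", {
  # a cherry with branches 1 and 3 becomes 2/2 (the mean rule)
  ch <- ultrametrize(read_newick("(a:1,b:3);"))
  expect_equal(ch$edge.length, c(2, 2))
  # fixed point on an already-ultrametric tree
  u <- ape::rcoal(8)
  u2 <- ultrametrize(u)
  expect_equal(phangorn::RF.dist(u, u2), 0)
  expect_equal(sort(u2$edge.length), sort(u$edge.length), tolerance = 1e-12)
  set.seed(321)
  for (i in 1:20) {
    tr <- midpoint_root(ape::rtree(sample(4:15, 1)))
    n <- ape::Ntip(tr)
    orig_depth <- ape::node.depth.edgelength(tr)[1:n]
    ut <- ultrametrize(tr)
    d <- ape::node.depth.edgelength(ut)[1:n]
    expect_lte(max(d) - min(d), 1e-9)
    # root height equals the mean original leaf depth
    expect_equal(max(d), mean(orig_depth), tolerance = 1e-9)
    expect_equal(phangorn::RF.dist(ut, tr), 0)
    expect_identical(ut$tip.label, tr$tip.label)
  }
})

test_that("cut_subtrees matches a brute-force node classifier", {
  tr <- ape::rcoal(6)
  tall <- cut_subtrees(tr, depth = max(node_heights(tr)) + 1)
  expect_equal(nrow(tall$roots), 1)
  expect_equal(sort(tall$membership$leaf_id), sort(tr$tip.label))
  fine <- cut_subtrees(tr, depth = 0)
  expect_equal(nrow(fine$roots), ape::Ntip(tr))

  expect_error(cut_subtrees(midpoint_root(ape::rtree(6)), 0.5),
               "not ultrametric")

  set.seed(331)
  for (i in 1:20) {
    tr <- ape::rcoal(sample(4:15, 1))
    h <- node_heights(tr)
    depth <- runif(1, 0, max(h) * 1.1)
    dec <- cut_subtrees(tr, depth)
    n <- ape::Ntip(tr)
    parent <- integer(n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    # brute-force scan: a node roots a subtree iff its height is <= depth
    # and it is the tree root or its parent exceeds depth
    expected_roots <- which(vapply(seq_along(h), function(v) {
      h[v] <= depth && (v == n + 1 || h[parent[v]] > depth)
    }, logical(1)))
    expect_setequal(dec$roots$node, expected_roots)
    # membership partitions the leaves
    expect_setequal(dec$membership$leaf_id, tr$tip.label)
    expect_equal(anyDuplicated(dec$membership$leaf_id), 0)
    # every subtree root at or below depth, parent above
    expect_true(all(dec$roots$height <= depth))
  }
})

test_that("constrained NJ keeps groups monophyletic", {
  set.seed(341)
  tr <- ape::rtree(9)
  dm <- ape::cophenetic.phylo(tr)
  # one group = all taxa: identical to plain NJ
  all_one <- constrained_nj(dm, list(g = rownames(dm)))
  expect_equal(phangorn::RF.dist(ape::unroot(all_one),
                                 ape::unroot(nj_tree(dm))), 0)
  # groups equal to true clades of the additive matrix: same topology
  rooted <- midpoint_root(tr)
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  below <- polswap:::.leaves_below(rooted)
  grp <- lapply(kids, function(v)
    rooted$tip.label[intersect(below[[v]], seq_len(ape::Ntip(rooted)))])
  names(grp) <- paste0("g", seq_along(grp))
  if (all(lengths(grp) >= 1)) {
    ct <- constrained_nj(dm, grp)
    expect_equal(phangorn::RF.dist(ape::unroot(ct), ape::unroot(tr)), 0)
  }
  # conflicting groups still end up monophyletic
  bad <- split(rownames(dm), rep(1:3, each = 3))
  names(bad) <- paste0("g", 1:3)
  ct2 <- constrained_nj(dm, bad)
  for (g in bad) expect_true(ape::is.monophyletic(ct2, g))
  expect_error(constrained_nj(dm, list(g1 = character(0),
                                       g2 = rownames(dm))), "empty")
  expect_error(constrained_nj(dm, list(g1 = rownames(dm)[1:3])), "partition")
})
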