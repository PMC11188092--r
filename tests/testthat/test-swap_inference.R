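summary_from_states <- function(states) {
  data.frame(genome_id = names(states),
             status = ifelse(is.na(states), "no-DNAP", "single-DNAP"),
             families = ifelse(is.na(states), "",
                               vapply(strsplit(states, "/"), `[`,
                                      character(1), 1)),
             n_dnaps = ifelse(is.na(states), 0L, 1L),
             state = states, stringsAsFactors = FALSE)
}

test_that("heterogeneous subtrees are detected by type", {
  tr <- ape::rcoal(6)
  dec <- cut_subtrees(tr, depth = max(node_heights(tr)) + 1)  # one subtree
  states <- setNames(rep("A/A1", 6), tr$tip.label)
  s <- summary_from_states(states)
  expect_equal(nrow(detect_heterogeneous_subtrees(dec, s)), 0)

  states[1] <- "B/B1"
  het <- detect_heterogeneous_subtrees(dec, summary_from_states(states))
  expect_equal(het$type, "swap")
  expect_equal(het$families, "A,B")

  # a genome with two different-family DNAPs yields a co-occurrence record
  s2 <- summary_from_states(setNames(rep("A/A1", 6), tr$tip.label))
  s2$status[2] <- "multi-DNAP"; s2$families[2] <- "A,divA1"
  s2$n_dnaps[2] <- 2L; s2$state[2] <- NA
  het2 <- detect_heterogeneous_subtrees(dec, s2)
  expect_equal(het2$type, "cooccurrence")
})

test_that("random labelings match a set-cardinality oracle", {
  set.seed(501)
  for (i in 1:50) {
    tr <- ape::rcoal(sample(4:10, 1))
    depth <- runif(1, 0, max(node_heights(tr)))
    dec <- cut_subtrees(tr, depth)
    fams <- c("A", "B", "C", NA)
    states <- setNames(paste0(sample(fams, ape::Ntip(tr), TRUE), "/x"),
                       tr$tip.label)
    states[grepl("^NA", states)] <- NA
    s <- summary_from_states(states)
    het <- detect_heterogeneous_subtrees(dec, s)
    swap_subtrees <- het$subtree_id[het$type == "swap"]
    for (st in unique(dec$membership$subtree_id)) {
      leaves <- dec$membership$leaf_id[dec$membership$subtree_id == st]
      fam_set <- unique(na.omit(vapply(strsplit(states[leaves], "/"),
                                       `[`, character(1), 1)))
      n_lab <- sum(!is.na(states[leaves]))
      expected <- length(leaves) >= 2 && n_lab >= 2 && length(fam_set) >= 2
      expect_equal(st %in% swap_subtrees, expected)
    }
  }
})

test_that("sister heterogeneous subtrees merge into one clade", {
  # balanced ultrametric 8-leaf tree, heights: leaves 0, cherries 0.1,
  # quartets 0.3, root 0.6
  nwk <- paste0("(((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2):0.3,",
                "((e:0.1,f:0.1):0.2,(g:0.1,h:0.1):0.2):0.3);")
  tr <- read_newick(nwk)
  dec <- cut_subtrees(tr, depth = 0.15)
  expect_equal(nrow(dec$roots), 4)
  states <- setNames(c("A/A1", "B/B1", "A/A1", "B/B1",
                       "A/A1", "A/A1", NA, NA), letters[1:8])
  s <- summary_from_states(states)
  het <- detect_heterogeneous_subtrees(dec, s)
  expect_equal(nrow(het), 2)
  clades <- group_swap_clades(tr, dec, het, s, max_clade_depth = 0.45)
  expect_equal(nrow(clades), 1)  # the two sister subtrees merge
  expect_equal(clades$n_genomes, 4)

  # siblings without any DNAP stop the ascent at the seed subtree
  states2 <- setNames(c("A/A1", "B/B1", NA, NA, NA, NA, NA, NA),
                      letters[1:8])
  s2 <- summary_from_states(states2)
  het2 <- detect_heterogeneous_subtrees(dec, s2)
  clades2 <- group_swap_clades(tr, dec, het2, s2, max_clade_depth = 0.45)
  expect_equal(nrow(clades2), 1)
  expect_equal(clades2$n_genomes, 2)  # clade == the seed subtree
})

test_that("swap clades are pairwise disjoint and contain their seeds", {
  set.seed(511)
  for (i in 1:20) {
    tr <- ape::rcoal(sample(6:14, 1))
    h <- max(node_heights(tr))
    dec <- cut_subtrees(tr, depth = h * 0.3)
    states <- setNames(sample(c("A/A1", "B/B1", "C/C1"), ape::Ntip(tr),
                              TRUE), tr$tip.label)
    s <- summary_from_states(states)
    het <- detect_heterogeneous_subtrees(dec, s)
    if (nrow(het) == 0) next
    clades <- group_swap_clades(tr, dec, het, s, max_clade_depth = h * 0.8)
    below <- polswap:::.leaves_below(tr)
    leaf_sets <- lapply(clades$root_node, function(v)
      tr$tip.label[intersect(below[[v]], seq_len(ape::Ntip(tr)))])
    if (length(leaf_sets) > 1) {
      for (a in seq_along(leaf_sets)) for (b in seq_along(leaf_sets)) {
        if (a < b)
          expect_equal(length(intersect(leaf_sets[[a]], leaf_sets[[b]])), 0)
      }
    }
    # every seed subtree is inside the clade that claimed it
    for (r in seq_len(nrow(clades))) {
      for (st in strsplit(clades$subtree_ids[r], ",")[[1]]) {
        seed_leaves <- dec$membership$leaf_id[dec$membership$subtree_id == st]
        expect_true(all(seed_leaves %in% leaf_sets[[r]]))
      }
    }
  }
})

test_that("parsimony events match trivial expectations", {
  tr <- read_newick("((g1:1,g2:1):1,g3:2);")
  r0 <- infer_swap_events(tr, setNames(rep("A/A1", 3), paste0("g", 1:3)))
  expect_equal(r0$min_changes, 0)
  expect_equal(nrow(r0$events), 0)

  r1 <- infer_swap_events(tr, setNames(c("A/A1", "B/B1", "B/B1"),
                                       paste0("g", 1:3)))
  expect_equal(r1$min_changes, 1)
  expect_equal(r1$events$child_label, "g1")
  expect_equal(r1$events$kind, "inter-family")

  # intra- vs inter-family kinds on constructed cases
  r2 <- infer_swap_events(tr, setNames(c("A/A1", "A/A2", "A/A2"),
                                       paste0("g", 1:3)))
  expect_equal(r2$events$kind, "intra-family")
  expect_error(infer_swap_events(tr, setNames("A/A1", "g1"),
                                 exclude_missing = FALSE), "unlabeled")
})

test_that("Sankoff minimum equals exhaustive enumeration", {
  set.seed(521)
  states <- c("A/A1", "A/A2", "B/B1")
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:8, 1))
    ls <- setNames(sample(states, ape::Ntip(tr), TRUE), tr$tip.label)
    got <- infer_swap_events(tr, ls)
    expect_equal(got$min_changes, brute_sankoff(tr, ls))
    expect_equal(nrow(got$events), got$min_changes)
    # invariance under state relabeling (unit costs)
    perm <- setNames(sample(states), states)
    got_perm <- infer_swap_events(tr, setNames(perm[ls], names(ls)))
    expect_equal(got_perm$min_changes, got$min_changes)
  }
})
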