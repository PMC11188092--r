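test_that("site likelihoods honor the model's closed-form limits", {
  fr <- setNames(rep(0.05, 20), Biostrings::AA_STANDARD)
  # two identical residues on a zero-length star: lnL = ln pi_a
  tr <- read_newick("(a:0,b:0);")
  expect_equal(site_lnl(c(a = "M", b = "M"), tr, fr), log(0.05))
  # infinite branches: residues become independent draws from pi
  trL <- read_newick("(a:1e6,b:1e6);")
  expect_equal(site_lnl(c(a = "M", b = "K"), trL, fr), 2 * log(0.05),
               tolerance = 1e-6)
  # gaps are missing data
  expect_equal(site_lnl(c(a = "M-", b = "MK"), tr, fr),
               c(log(0.05), log(0.05)))
})

test_that("pruning equals brute-force summation over internal states", {
  set.seed(601)
  aln <- setNames(vapply(1:4, function(i) random_aa(10), character(1)),
                  c("a", "b", "c", "d"))
  tr <- read_newick("((a:0.12,b:0.27):0.08,(c:0.31,d:0.05):0.11);")
  fr <- alignment_freqs(aln)
  got <- site_lnl(aln, tr, fr)
  aa <- Biostrings::AA_STANDARD
  beta <- 1 / (1 - sum(fr^2))
  P <- function(t) exp(-beta * t) * diag(20) +
    (1 - exp(-beta * t)) * matrix(fr, 20, 20, byrow = TRUE)
  Pu <- P(0.08); Pv <- P(0.11)
  Pl <- lapply(c(a = 0.12, b = 0.27, c = 0.31, d = 0.05), P)
  chars <- do.call(rbind, strsplit(aln, ""))
  want <- vapply(1:10, function(s) {
    idx <- match(chars[, s], aa)
    tot <- 0
    for (u in 1:20) for (v in 1:20) {
      tot <- tot + sum(fr * Pu[, u] * Pv[, v]) *
        Pl$a[u, idx[1]] * Pl$b[u, idx[2]] * Pl$c[v, idx[3]] * Pl$d[v, idx[4]]
    }
    log(tot)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
  # total log-likelihood is invariant under site permutation
  perm <- sample(10)
  aln_p <- setNames(vapply(aln, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1)),
    names(aln))
  expect_equal(sum(site_lnl(aln_p, tr, fr)), sum(got))
})

test_that("AU test: ties give 0.5, uniform dominance rejects, reproducibly", {
  set.seed(611)
  base <- rnorm(400, -3)
  tied <- cbind(t1 = base, t2 = base)
  res <- au_test(tied, B = 2000, seed = 11)
  expect_equal(res$table$p_au, c(0.5, 0.5), tolerance = 0.02)
  expect_true(all(abs(res$bp - 0.5) < 1e-12))  # exact tie split

  dom <- cbind(best = base + 0.1, worse = base)
  res2 <- au_test(dom, B = 2000, seed = 12)
  expect_equal(res2$table$p_au[res2$table$topology == "worse"], 1 / 2001)
  expect_equal(res2$table$p_au[res2$table$topology == "best"], 1 - 1 / 2001)

  # bp sums to 1 at every scale; identical seeds are bit-identical
  noisy <- cbind(t1 = base + rnorm(400, 0, 0.5), t2 = base)
  r1 <- au_test(noisy, B = 500, seed = 13)
  r2 <- au_test(noisy, B = 500, seed = 13)
  expect_identical(r1, r2)
  expect_equal(unname(colSums(r1$bp)), rep(1, length(r1$scales)))
  expect_error(au_test(noisy, scales = 1, B = 100, seed = 1), "scales")
  expect_error(au_test(noisy[, 1, drop = FALSE], B = 100, seed = 1),
               "topologies")
})

test_that("constrained-vs-unconstrained comparison behaves at the ends", {
  set.seed(621)
  # a clade with a real split: groups equal to true clades -> both
  # topologies agree, p_au near 0.5 for both
  cfg <- small_sim_config(n_genomes = 6, n_swaps = 0)
  sim <- simulate_clade(cfg, seed = 622)
  # concatenate all genes for a long, low-noise alignment
  mat <- do.call(rbind, lapply(sim$truth$alignments, function(a)
    a[sim$truth$tree$tip.label]))
  aln <- setNames(apply(mat, 2, paste, collapse = ""),
                  sim$truth$tree$tip.label)
  rooted <- sim$truth$tree
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  below <- polswap:::.leaves_below(rooted)
  grp <- lapply(kids, function(v)
    rooted$tip.label[intersect(below[[v]], seq_len(ape::Ntip(rooted)))])
  names(grp) <- paste0("g", seq_along(grp))
  # additive input: both topologies recover the generating tree exactly
  td <- ape::cophenetic.phylo(rooted)[names(aln), names(aln)]
  res <- compare_constrained(aln, grp, dm = td, B = 2000, seed = 623)
  expect_equal(phangorn::RF.dist(attr(res, "trees")$unconstrained,
                                 attr(res, "trees")$constrained), 0)
  expect_equal(res$table$p_au, c(0.5, 0.5), tolerance = 0.1)
  # 3-taxon alignment: only one unrooted topology
  aln3 <- aln[1:3]
  res3 <- compare_constrained(aln3, list(g1 = names(aln3)[1:2],
                                         g2 = names(aln3)[3]),
                              B = 1000, seed = 624)
  expect_equal(res3$table$p_au, c(0.5, 0.5), tolerance = 0.1)
})

test_that("F81 distance correction inverts the model's expected divergence", {
  set.seed(631)
  cfg <- small_sim_config(n_genomes = 2, n_swaps = 0, tree_height = 0.3,
                          gene_len_range = c(400, 500))
  sim <- simulate_clade(cfg, seed = 632)
  aln <- sim$truth$alignments[[1]]
  d <- f81_distance_matrix(aln)
  # the two leaves sit 2 * 0.3 substitutions apart in expectation
  expect_equal(d[1, 2], 0.6, tolerance = 0.12)
})
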