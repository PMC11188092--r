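test_that("align_pair matches the independent DP oracle on random pairs", {
  suppressMessages(requireNamespace("Biostrings"))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(51)
  for (i in 1:25) {
    q <- random_aa(sample(40:150, 1))
    s <- random_aa(sample(40:150, 1))
    got <- align_pair(q, s)
    want <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    expect_equal(got$score, Biostrings::score(want))
  }
})

test_that("align_pair on identical sequences is a perfect full-cover hit", {
  p <- random_aa(100)
  a <- align_pair(p, p)
  expect_equal(a$identity, 1)
  expect_equal(a$query_cov, 1)
  expect_gt(a$bitscore, 100)
  # E-value scales linearly with the search space and vanishes in the limit
  expect_equal(align_pair(p, p, search_space = 0)$evalue, 0)
  expect_equal(align_pair(p, p, search_space = 2e6)$evalue,
               2 * align_pair(p, p, search_space = 1e6)$evalue)
})

test_that("self-alignment dominates alphabet shuffles", {
  set.seed(61)
  p <- random_aa(120)
  self <- align_pair(p, p)$score
  shuf <- vapply(1:20, function(i) {
    s <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    align_pair(p, s)$score
  }, numeric(1))
  expect_true(all(shuf < self))
})

make_orf_table <- function(proteins, genome_id, spacing = 1000) {
  n <- length(proteins)
  data.frame(genome_id = genome_id,
             orf_id = sprintf("%s_o%02d", genome_id, seq_len(n)),
             start = (seq_len(n) - 1) * spacing,
             end = (seq_len(n) - 1) * spacing + nchar(proteins) * 3 + 3,
             strand = "+", frame = 0L, protein = proteins,
             stringsAsFactors = FALSE)
}

test_that("RBH on identical proteomes pairs every protein with its copy", {
  set.seed(71)
  prots <- vapply(1:6, function(i) random_aa(80), character(1))
  oa <- make_orf_table(prots, "A")
  ob <- make_orf_table(prots, "B")
  r <- reciprocal_best_hits(oa, ob)
  expect_equal(nrow(r), 6)
  expect_equal(sub("A_", "", r$query_id), sub("B_", "", r$subject_id))
  expect_equal(r$identity, rep(1, 6))
  # empty side
  expect_equal(nrow(reciprocal_best_hits(oa[0, ], ob)), 0)
})

test_that("RBH equals the brute-force mutual-argmax oracle and is symmetric", {
  suppressMessages(requireNamespace("Biostrings"))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(81)
  # two related proteomes: half shared-descent, half unrelated
  base <- vapply(1:10, function(i) random_aa(90), character(1))
  pa <- c(base, vapply(1:10, function(i) random_aa(90), character(1)))
  pb <- c(vapply(base, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < 0.3
    v[hit] <- sample(Biostrings::AA_STANDARD, sum(hit), TRUE)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE),
  vapply(1:10, function(i) random_aa(90), character(1)))
  oa <- make_orf_table(pa, "A")
  ob <- make_orf_table(pb, "B")
  got <- reciprocal_best_hits(oa, ob, seed_k = 0)

  # oracle: all-vs-all Biostrings scores, mutual argmax, thresholds
  smat <- matrix(NA_real_, 20, 20)
  for (i in 1:20) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pb), Biostrings::AAString(pa[i]),
      type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1)
    smat[i, ] <- Biostrings::score(al)
  }
  pairs <- character(0)
  for (i in 1:20) {
    j <- which.max(smat[i, ])
    if (which.max(smat[, j]) == i) {
      bits <- bit_score(smat[i, j])
      e_ab <- evalue_from_bits(bits, 20 * mean(nchar(pb)) * nchar(pa[i]))
      e_ba <- evalue_from_bits(bits, 20 * mean(nchar(pa)) * nchar(pb[j]))
      if (e_ab <= 1e-4 && e_ba <= 1e-4)
        pairs <- c(pairs, paste(oa$orf_id[i], ob$orf_id[j]))
    }
  }
  # oracle ignores coverage; verify coverage did not drop extra pairs here
  expect_setequal(paste(got$query_id, got$subject_id), pairs)
  # the seeded search agrees with the exact search on these proteomes
  seeded <- reciprocal_best_hits(oa, ob, seed_k = 4, seed_min = 2)
  expect_equal(seeded, got)
  # symmetry: swapping sides transposes the pair list
  rev <- reciprocal_best_hits(ob, oa, seed_k = 0)
  expect_setequal(paste(rev$subject_id, rev$query_id),
                  paste(got$query_id, got$subject_id))
})

test_that("coverage is an interval union bounded by genome length", {
  orfs_a <- data.frame(genome_id = "A", orf_id = c("o1", "o2"),
                       start = c(0L, 150L), end = c(300L, 450L),
                       strand = "+", frame = 0L, protein = "M",
                       stringsAsFactors = FALSE)
  orfs_b <- data.frame(genome_id = "B", orf_id = "p1", start = 0L,
                       end = 300L, strand = "+", frame = 0L, protein = "M",
                       stringsAsFactors = FALSE)
  rbh1 <- data.frame(query_id = "o1", subject_id = "p1")
  cov1 <- rbh_coverage(rbh1, orfs_a, orfs_b, 1000, 500)
  expect_equal(cov1$c_ab, 300L)
  rbh2 <- data.frame(query_id = c("o1", "o2"), subject_id = c("p1", "p1"))
  cov2 <- rbh_coverage(rbh2, orfs_a, orfs_b, 1000, 500)
  expect_equal(cov2$c_ab, 450L)  # union, not 600

  set.seed(91)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    st <- sample(0:900, n)
    en <- st + sample(30:120, n, replace = TRUE)
    oa <- data.frame(genome_id = "A", orf_id = sprintf("o%d", 1:n),
                     start = st, end = en, strand = "+", frame = 0L,
                     protein = "M", stringsAsFactors = FALSE)
    rbh <- data.frame(query_id = oa$orf_id, subject_id = "p1")
    cov <- rbh_coverage(rbh, oa, orfs_b, 1200, 500)
    expect_equal(cov$c_ab, bitmap_union(st, en, 1200))
    expect_lte(cov$c_ab, cov$l_a)
  }
})
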