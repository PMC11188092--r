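make_ref_set <- function(seed = 401) {
  set.seed(seed)
  cfg <- small_sim_config()
  donors <- make_donor_pools(cfg)
  refs <- Biostrings::AAStringSet(vapply(donors, function(d)
    paste(d$dnap, collapse = ""), character(1)))
  names(refs) <- paste0("ref_", gsub("/", "_", names(donors)))
  labels <- data.frame(ref_id = names(refs),
                       family = vapply(donors, `[[`, character(1), "family"),
                       clade = vapply(donors, `[[`, character(1), "clade"),
                       stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  list(refs = refs, labels = labels, motifs = attr(donors, "motifs"),
       donors = donors, config = cfg)
}

test_that("assign_family recovers exact and divergent family members", {
  rs <- make_ref_set()
  q <- as.character(rs$refs[["ref_A_A1"]])
  call <- assign_family(q, rs$refs, rs$labels)
  expect_equal(call$family, "A")
  expect_equal(call$clade, "A1")
  expect_equal(call$best_ref, "ref_A_A1")
  # ~40% identity divergent copy of a family-B donor still maps to family B
  set.seed(402)
  freqs <- rs$config$freqs
  beta <- 1 / (1 - sum(freqs^2))
  div <- polswap:::.evolve_protein(rs$donors[["B/B1"]]$dnap, 1.2, freqs,
                                   beta, attr(rs$donors, "invariant"))
  call2 <- assign_family(paste(div, collapse = ""), rs$refs, rs$labels)
  expect_equal(call2$family, "B")
})

test_that("random sequences are never assigned a family", {
  rs <- make_ref_set()
  set.seed(403)
  for (i in 1:10) {
    call <- assign_family(random_aa(100), rs$refs, rs$labels)
    expect_equal(call$family, "none")
  }
})

test_that("catalytic screening reads motif residues through the alignment", {
  rs <- make_ref_set()
  ref_id <- "ref_A_A1"
  q <- as.character(rs$refs[[ref_id]])
  call <- assign_family(q, rs$refs, rs$labels)
  st <- check_catalytic(q, call, rs$refs, rs$motifs)
  expect_true(all(st$status == "intact"))

  # mutate the three Exo aspartates to alanine: Exo degraded, Pol intact
  mset <- rs$motifs[rs$motifs$ref_id == ref_id, ]
  exo_pos <- mset$position[startsWith(mset$motif, "Exo")]
  v <- strsplit(q, "")[[1]]
  v[exo_pos] <- "A"
  mut <- paste(v, collapse = "")
  st2 <- check_catalytic(mut, assign_family(mut, rs$refs, rs$labels),
                         rs$refs, rs$motifs)
  expect_true(all(st2$status[startsWith(st2$motif, "Exo")] == "degraded"))
  expect_true(all(st2$status[startsWith(st2$motif, "Pol")] == "intact"))

  # single-position mutants agree with a direct position lookup
  set.seed(404)
  for (i in 1:20) {
    pos <- sample(mset$position, 1)
    row <- mset[mset$position == pos, ][1, ]
    v <- strsplit(q, "")[[1]]
    v[pos] <- sample(setdiff(Biostrings::AA_STANDARD, row$residues), 1)
    m <- paste(v, collapse = "")
    stm <- check_catalytic(m, assign_family(m, rs$refs, rs$labels),
                           rs$refs, rs$motifs)
    expect_equal(stm$status[stm$motif == row$motif], "degraded")
    expect_true(all(stm$status[stm$motif != row$motif] == "intact"))
  }
})

test_that("retention keeps intact near-full-length calls only", {
  rs <- make_ref_set()
  q <- as.character(rs$refs[["ref_A_A1"]])
  orfs <- data.frame(genome_id = "g", orf_id = "p1", start = 0L,
                     end = nchar(q) * 3 + 3, strand = "+", frame = 0L,
                     protein = q, stringsAsFactors = FALSE)
  calls <- annotate_orfs(orfs, rs$refs, rs$labels)
  prot <- Biostrings::AAStringSet(setNames(q, "p1"))
  kept <- retain_active_calls(calls, prot, rs$refs, rs$motifs)
  expect_equal(nrow(kept), 1)
  # degrade a Pol motif: the call is dropped
  mset <- rs$motifs[rs$motifs$ref_id == "ref_A_A1", ]
  pol_pos <- mset$position[startsWith(mset$motif, "Pol")][1]
  v <- strsplit(q, "")[[1]]; v[pol_pos] <- "G"
  orfs$protein <- paste(v, collapse = "")
  calls2 <- annotate_orfs(orfs, rs$refs, rs$labels)
  prot2 <- Biostrings::AAStringSet(setNames(orfs$protein, "p1"))
  expect_equal(nrow(retain_active_calls(calls2, prot2, rs$refs, rs$motifs)), 0)
})

test_that("per-genome heterogeneity summaries cover all three statuses", {
  calls <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    genome_id = c("g1", "g2", "g2"),
    family = c("A", "A", "divA1"),
    clade = c("A1", "A1", "dA1"),
    stringsAsFactors = FALSE)
  s <- classify_heterogeneity(calls, genome_ids = c("g1", "g2", "g3"))
  expect_equal(s$status, c("single-DNAP", "multi-DNAP", "no-DNAP"))
  expect_equal(s$families[2], "A,divA1")
  expect_equal(s$state[1], "A/A1")
  expect_equal(s$n_dnaps, c(1L, 2L, 0L))
})
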