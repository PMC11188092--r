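# Independent oracles and small generators shared across the test files.
# Every oracle here is deliberately brute-force and independent of the
# package's own implementation path.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force six-frame ORF oracle: enumerate every ATG, extend to the first
# in-frame stop, filter by length, then drop strictly nested intervals
brute_force_orfs <- function(seq_chr, min_len = 75) {
  scan1 <- function(s) {
    n <- nchar(s)
    hits <- list()
    for (start in seq_len(max(n - 2, 0))) {
      if (substring(s, start, start + 2) != "ATG") next
      p <- start
      repeat {
        p <- p + 3
        if (p + 2 > n) { p <- NA; break }
        if (substring(s, p, p + 2) %in% c("TAA", "TAG", "TGA")) break
      }
      if (is.na(p)) next
      len <- p + 3 - start
      if (len >= min_len)
        hits[[length(hits) + 1]] <- c(start - 1, p + 2)
    }
    hits
  }
  fwd <- scan1(seq_chr)
  L <- nchar(seq_chr)
  rev <- lapply(scan1(revcomp_chr(seq_chr)), function(h) c(L - h[2], L - h[1]))
  iv <- rbind(
    if (length(fwd)) cbind(do.call(rbind, fwd), strand = 1) else NULL,
    if (length(rev)) cbind(do.call(rbind, rev), strand = 2) else NULL
  )
  if (is.null(iv)) return(iv)
  df <- data.frame(start = iv[, 1], end = iv[, 2], strand = iv[, 3])
  len <- df$end - df$start
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- !any(df$start <= df$start[i] & df$end >= df$end[i] &
                      len > len[i])
  }
  out <- df[keep, c("start", "end", "strand")]
  out[order(out$start, out$end, out$strand), ]
}

# exhaustive Sankoff oracle: minimum number of state changes over every
# internal-node assignment
brute_sankoff <- function(tree, leaf_states) {
  sts <- sort(unique(unname(leaf_states)))
  n <- ape::Ntip(tree)
  grid <- expand.grid(rep(list(sts), tree$Nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- c(unname(leaf_states[tree$tip.label]),
             unlist(grid[r, ], use.names = FALSE))
    best <- min(best, sum(asg[tree$edge[, 1]] != asg[tree$edge[, 2]]))
  }
  best
}

# per-position marking oracle for interval-union length
bitmap_union <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
  sum(covered)
}

# does the family-separating constraint measurably conflict with the true
# tree? (max distortion of a true pairwise distance by the constrained
# topology's least-squares fit, threshold 0.1 substitutions/site)
strong_signal_clade <- function(sim, groups) {
  td <- ape::cophenetic.phylo(sim$truth$tree)
  con <- constrained_nj(td, groups)
  fit <- phangorn::nnls.tree(td, ape::unroot(con), method = "unrooted")
  resid <- abs(ape::cophenetic.phylo(fit)[rownames(td), colnames(td)] - td)
  max(resid) >= 0.1
}

# small fast simulator settings for module-level tests
small_sim_config <- function(...) {
  defaults <- list(n_genomes = 4, n_genes = 6, gene_len_range = c(80, 140),
                   dnap_len = 180, block_len = 3, en_bloc_k = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
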