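# Pairwise protein alignment, reciprocal-best-hit detection between ORF
# complements, and RBH coverage accounting.
#
# The aligner is Smith-Waterman with BLOSUM62 and affine gaps (open 11,
# extend 1, BLAST convention), compiled in src/. Bit scores use the gapped
# BLOSUM62 constants lambda = 0.267, K = 0.041; E = search_space * 2^-bits.

.sw_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.sw_env$blosum62)) {
    data("BLOSUM62", package = "Biostrings", envir = .sw_env)
    .sw_env$blosum62 <- .sw_env$BLOSUM62
  }
  .sw_env$blosum62
}

# encode sequences as 0-based indices into the scoring matrix alphabet;
# letters not in the alphabet map to wildcard
.encode_seqs <- function(seqs, alphabet, wildcard = "X") {
  wi <- match(wildcard, alphabet)
  lapply(as.character(seqs), function(s) {
    i <- match(strsplit(s, "", fixed = TRUE)[[1]], alphabet)
    i[is.na(i)] <- wi
    as.integer(i - 1L)
  })
}

#' Convert a raw Smith-Waterman score to a bit score
#'
#' Uses the gapped BLOSUM62 Karlin-Altschul constants lambda = 0.267,
#' K = 0.041.
#'
#' @param score Raw alignment score(s).
#' @return Bit score(s).
#' @export
bit_score <- function(score) {
  (0.267 * score - log(0.041)) / log(2)
}

#' E-value from a bit score and a search-space size
#'
#' @param bits Bit score(s).
#' @param search_space Effective search-space size (see
#'   [reciprocal_best_hits()] for the surrogate used by the pipeline).
#' @return Expected number of chance hits.
#' @export
evalue_from_bits <- function(bits, search_space) {
  search_space * 2^(-bits)
}

#' Align a pair of protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1). `query_cov` is the aligned query span divided by the
#' query length; `identity` is identical columns over alignment columns.
#'
#' @param query,subject Protein sequences (character or `AAString`).
#' @param search_space Effective search space for the E-value; defaults to
#'   `nchar(query) * nchar(subject)`.
#' @param details If `TRUE`, attach the per-column position map as attribute
#'   `"columns"` (matrix with rows `q` and `s`; 0 marks a gap).
#' @return A one-row data frame: `score`, `bitscore`, `evalue`, `query_cov`,
#'   `identity`, `qstart`, `qend`, `sstart`, `send` (1-based inclusive).
#' @export
align_pair <- function(query, subject, search_space = NULL, details = FALSE) {
  query <- as.character(query); subject <- as.character(subject)
  if (nchar(query) == 0 || nchar(subject) == 0)
    stop("empty sequence in align_pair")
  if (is.null(search_space))
    search_space <- nchar(query) * nchar(subject)
  mat <- .blosum62()
  enc <- .encode_seqs(c(query, subject), rownames(mat))
  al <- .sw_full(enc[[1]], enc[[2]], mat, 11, 1)
  bits <- bit_score(al$score)
  out <- data.frame(
    score = al$score,
    bitscore = bits,
    evalue = evalue_from_bits(bits, search_space),
    query_cov = if (al$length > 0) (al$qend - al$qstart + 1) / nchar(query) else 0,
    identity = if (al$length > 0) al$nmatch / al$length else 0,
    qstart = al$qstart, qend = al$qend,
    sstart = al$sstart, send = al$send
  )
  if (details)
    attr(out, "columns") <- rbind(q = al$qcols, s = al$scols)
  out
}

# distinct k-mers of each sequence, packed into integers (base-32 on the
# alphabet index); used by the BLAST-like seeding prefilter
.kmer_keys <- function(seqs, k) {
  alph <- c(Biostrings::AA_STANDARD, "X", "*")
  lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(integer(0))
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], alph)
    idx[is.na(idx)] <- 21L
    key <- integer(n - k + 1)
    for (o in 0:(k - 1)) key <- key * 32L + idx[(1 + o):(n - k + 1 + o)]
    unique(key)
  })
}

# count distinct shared k-mers for every (i in a) x (j in b) pair;
# returns an na x nb integer matrix
.shared_kmer_counts <- function(ka, kb) {
  na <- length(ka); nb <- length(kb)
  counts <- matrix(0L, na, nb)
  va <- data.frame(g = unlist(ka),
                   i = rep(seq_len(na), lengths(ka)))
  vb <- data.frame(g = unlist(kb),
                   j = rep(seq_len(nb), lengths(kb)))
  common <- intersect(va$g, vb$g)
  if (length(common) == 0) return(counts)
  la <- split(va$i[va$g %in% common], va$g[va$g %in% common])
  lb <- split(vb$j[vb$g %in% common], vb$g[vb$g %in% common])
  lb <- lb[names(la)]
  for (g in seq_along(la)) {
    ii <- la[[g]]; jj <- lb[[g]]
    counts[ii, jj] <- counts[ii, jj] + 1L
  }
  counts
}

# Smith-Waterman scores for selected pairs of two encoded sequence lists
.sw_pair_scores <- function(enc_a, enc_b, pairs) {
  mat <- .blosum62()
  .sw_scores(enc_a, enc_b, pairs, mat, 11, 1)
}

#' Reciprocal best hits between two ORF complements
#'
#' A pair (x, y) is reported when y is x's best-scoring hit among the ORFs of
#' genome B and x is y's best among A (ties broken by lexicographically
#' smaller subject id), and both directional hits satisfy the query-coverage
#' and E-value thresholds. The E-value search space for direction A->B is
#' `n_B * mean(length_B) * length(query)`, a monotone surrogate for the
#' BLASTP default.
#'
#' With `seed_k > 0` the all-vs-all scan is restricted, BLAST-fashion, to
#' pairs sharing at least `seed_min` distinct k-mers; `seed_k = 0` scores
#' every pair exactly.
#'
#' @param orfs_a,orfs_b ORF tables from [find_orfs()] (single genome each).
#' @param min_query_cov Minimum aligned fraction of the query, both
#'   directions (default 0.5).
#' @param max_evalue Maximum E-value, both directions (default 1e-4).
#' @param seed_k Seed k-mer length for the prefilter (default 4; 0 disables).
#' @param seed_min Minimum number of shared distinct k-mers (default 2).
#' @return Data frame, one row per RBH pair: ids, raw score, bit score,
#'   directional E-values and query coverages, identity.
#' @export
reciprocal_best_hits <- function(orfs_a, orfs_b, min_query_cov = 0.5,
                                 max_evalue = 1e-4, seed_k = 4, seed_min = 2) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), bitscore = numeric(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      qcov_ab = numeric(), qcov_ba = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(orfs_a) == 0 || nrow(orfs_b) == 0) return(empty)
  pa <- orfs_a$protein; pb <- orfs_b$protein
  na <- length(pa); nb <- length(pb)
  mat <- .blosum62()
  enc_a <- .encode_seqs(pa, rownames(mat))
  enc_b <- .encode_seqs(pb, rownames(mat))
  if (seed_k > 0) {
    counts <- .shared_kmer_counts(.kmer_keys(pa, seed_k), .kmer_keys(pb, seed_k))
    cand <- which(counts >= seed_min, arr.ind = TRUE)
  } else {
    cand <- as.matrix(expand.grid(row = seq_len(na), col = seq_len(nb)))
  }
  if (nrow(cand) == 0) return(empty)
  scores <- .sw_pair_scores(enc_a, enc_b, cand)
  smat <- matrix(-Inf, na, nb)
  smat[cand] <- scores
  # best hit per query (A->B) and per subject (B->A); score ties broken by
  # lexicographically smaller partner id
  best_of <- function(score_rows, ids) {
    apply(score_rows, 1, function(r) {
      if (all(!is.finite(r))) return(NA_integer_)
      mx <- max(r)
      hit <- which(r == mx)
      hit[order(ids[hit])][1]
    })
  }
  best_ab <- best_of(smat, orfs_b$orf_id)
  best_ba <- best_of(t(smat), orfs_a$orf_id)
  mutual <- which(!is.na(best_ab) &
                  !is.na(best_ba[best_ab]) &
                  best_ba[best_ab] == seq_len(na))
  if (length(mutual) == 0) return(empty)
  mean_la <- mean(nchar(pa)); mean_lb <- mean(nchar(pb))
  rows <- lapply(mutual, function(i) {
    j <- best_ab[i]
    al <- .sw_full(enc_a[[i]], enc_b[[j]], mat, 11, 1)
    bits <- bit_score(al$score)
    e_ab <- evalue_from_bits(bits, nb * mean_lb * nchar(pa[i]))
    e_ba <- evalue_from_bits(bits, na * mean_la * nchar(pb[j]))
    qcov_ab <- if (al$length > 0) (al$qend - al$qstart + 1) / nchar(pa[i]) else 0
    qcov_ba <- if (al$length > 0) (al$send - al$sstart + 1) / nchar(pb[j]) else 0
    data.frame(query_id = orfs_a$orf_id[i], subject_id = orfs_b$orf_id[j],
               score = al$score, bitscore = bits,
               evalue_ab = e_ab, evalue_ba = e_ba,
               qcov_ab = qcov_ab, qcov_ba = qcov_ba,
               identity = if (al$length > 0) al$nmatch / al$length else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$qcov_ab >= min_query_cov & out$qcov_ba >= min_query_cov &
    out$evalue_ab <= max_evalue & out$evalue_ba <= max_evalue
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RBH coverage of a genome pair
#'
#' `c_ab` is the number of genome-A positions covered by the union of the
#' genomic intervals of A-side ORFs participating in any RBH pair
#' (overlapping ORFs counted once); symmetrically for `c_ba`.
#'
#' @param rbh RBH table from [reciprocal_best_hits()].
#' @param orfs_a,orfs_b The ORF tables the RBH search was run on.
#' @param genome_a,genome_b The genome sequences (or their integer lengths).
#' @return A list with elements `c_ab`, `c_ba`, `l_a`, `l_b`.
#' @export
rbh_coverage <- function(rbh, orfs_a, orfs_b, genome_a, genome_b) {
  glen <- function(g) if (is.numeric(g)) as.integer(g) else nchar(as.character(g))
  union_len <- function(orfs, ids) {
    sel <- orfs[orfs$orf_id %in% ids, , drop = FALSE]
    if (nrow(sel) == 0) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = sel$start + 1L, end = sel$end))))
  }
  list(c_ab = union_len(orfs_a, rbh$query_id),
       c_ba = union_len(orfs_b, rbh$subject_id),
       l_a = glen(genome_a), l_b = glen(genome_b))
}
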