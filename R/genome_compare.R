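# Fragment-based average nucleotide identity for closely related genome
# pairs (OrthoANI-style reciprocal fragment pairing). Each genome is split
# into consecutive non-overlapping fragments; fragments are placed on the
# other genome by 12-mer seeding and aligned locally against a window around
# the seeded diagonal (match +1, mismatch -1, gap open 5, extend 2).

.dna_matrix <- function() {
  alph <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(alph, alph))
  diag(m) <- 1
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

.encode_dna <- function(s) {
  i <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T", "N"))
  i[is.na(i)] <- 5L
  as.integer(i - 1L)
}

# positions (1-based) of each k-mer of s, as an environment keyed by k-mer
.kmer_index <- function(s, k) {
  n <- nchar(s)
  env <- new.env(parent = emptyenv(), size = max(16L, n))
  if (n < k) return(env)
  kmers <- substring(s, 1:(n - k + 1), k:n)
  list2env(split(seq_along(kmers), kmers), envir = env)
}

# best diagonal offset of query fragment on the indexed subject, by vote
.seed_offset <- function(frag, idx, k) {
  n <- nchar(frag)
  if (n < k) return(NULL)
  starts <- seq(1, n - k + 1, by = 7L)  # sparse query seeds
  kmers <- substring(frag, starts, starts + k - 1)
  offs <- integer(0)
  for (i in seq_along(kmers)) {
    hits <- idx[[kmers[i]]]
    if (!is.null(hits)) offs <- c(offs, hits - starts[i])
  }
  if (length(offs) == 0) return(NULL)
  # cluster offsets within a small band and take the most-voted one
  tb <- sort(table(round(offs / 25)), decreasing = TRUE)
  band <- as.integer(names(tb)[1])
  sel <- offs[round(offs / 25) == band]
  list(offset = as.integer(round(stats::median(sel))), votes = length(sel))
}

#' Average nucleotide identity between two genomes
#'
#' Each genome is cut into consecutive non-overlapping fragments of
#' `fragment_len` nt (a trailing shorter fragment is discarded). Every
#' fragment is placed on the other genome by k-mer seeding (both strands)
#' and aligned against a window around the seeded position; fragments
#' reaching `min_frag_identity` over at least `min_frag_cov` of their length
#' are retained, paired by reciprocal best fragment, and the ANI is 100
#' times the mean identity over reciprocal pairs, averaged over both
#' directions.
#'
#' @param a,b Genome sequences (character, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @param fragment_len Fragment length in nt (default 1000).
#' @param min_frag_identity Minimum alignment identity to retain a fragment
#'   (default 0.7).
#' @param min_frag_cov Minimum aligned fraction of the fragment (default
#'   0.7).
#' @param seed_kmer Seeding k-mer length (default 12).
#' @param window_margin Extra subject sequence on both sides of the seeded
#'   window (default 200 nt).
#' @return List of class `ani_result`: `ani` (percent, `NA` when below
#'   detection), `below_detection`, `n_fragments_used`, `fragment_len`,
#'   per-direction means.
#' @export
ani <- function(a, b, fragment_len = 1000, min_frag_identity = 0.7,
                min_frag_cov = 0.7, seed_kmer = 12, window_margin = 200) {
  sa <- .as_dna_chr(a); sb <- .as_dna_chr(b)
  if (nchar(sa) < fragment_len || nchar(sb) < fragment_len)
    stop("both genomes must be at least one fragment long")
  da <- .ani_direction(sa, sb, fragment_len, min_frag_identity, min_frag_cov,
                       seed_kmer, window_margin)
  db <- .ani_direction(sb, sa, fragment_len, min_frag_identity, min_frag_cov,
                       seed_kmer, window_margin)
  # reciprocal best pairing at the fragment level
  rec_ab <- .reciprocal_fragments(da, db)
  rec_ba <- .reciprocal_fragments(db, da)
  below <- length(rec_ab) == 0 && length(rec_ba) == 0
  mean_ab <- if (length(rec_ab)) mean(da$identity[rec_ab]) else NA_real_
  mean_ba <- if (length(rec_ba)) mean(db$identity[rec_ba]) else NA_real_
  out <- list(
    ani = if (below) NA_real_ else 100 * mean(c(mean_ab, mean_ba), na.rm = TRUE),
    below_detection = below,
    n_fragments_used = length(rec_ab) + length(rec_ba),
    fragment_len = fragment_len,
    mean_identity_ab = mean_ab, mean_identity_ba = mean_ba
  )
  class(out) <- "ani_result"
  out
}

.as_dna_chr <- function(x) {
  if (methods::is(x, "DNAStringSet")) x <- x[[1]]
  toupper(as.character(x))
}

# one direction: query fragments of qs against subject ss.
# returns per-fragment: retained flag, identity, subject fragment index
.ani_direction <- function(qs, ss, fragment_len, min_id, min_cov,
                           seed_kmer, margin) {
  nfrag <- nchar(qs) %/% fragment_len
  ss_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ss)))
  idx_f <- .kmer_index(ss, seed_kmer)
  idx_r <- .kmer_index(ss_rc, seed_kmer)
  mat <- .dna_matrix()
  slen <- nchar(ss)
  identity <- rep(NA_real_, nfrag)
  sfrag <- rep(NA_integer_, nfrag)
  for (i in seq_len(nfrag)) {
    frag <- substring(qs, (i - 1) * fragment_len + 1, i * fragment_len)
    sf <- .seed_offset(frag, idx_f, seed_kmer)
    sr <- .seed_offset(frag, idx_r, seed_kmer)
    use_rc <- !is.null(sr) && (is.null(sf) || sr$votes > sf$votes)
    hit <- if (use_rc) sr else sf
    if (is.null(hit)) next
    subj <- if (use_rc) ss_rc else ss
    ws <- max(1, hit$offset + 1 - margin)
    we <- min(slen, hit$offset + fragment_len + margin)
    if (we <= ws) next
    al <- .sw_full(.encode_dna(frag), .encode_dna(substring(subj, ws, we)),
                   mat, 5, 2)
    if (al$length == 0) next
    idv <- al$nmatch / al$length
    cov <- (al$qend - al$qstart + 1) / fragment_len
    if (idv < min_id || cov < min_cov) next
    # aligned subject midpoint in forward-strand coordinates
    mid <- ws + (al$sstart + al$send) / 2 - 1
    if (use_rc) mid <- slen - mid + 1
    identity[i] <- idv
    sfrag[i] <- min(max(1L, as.integer(ceiling(mid / fragment_len))),
                    max(1L, slen %/% fragment_len))
  }
  list(identity = identity, sfrag = sfrag, nfrag = nfrag)
}

# indices of query fragments whose best subject fragment maps back to them
.reciprocal_fragments <- function(dq, ds) {
  ok <- which(!is.na(dq$sfrag))
  keep <- integer(0)
  for (i in ok) {
    j <- dq$sfrag[i]
    if (j <= length(ds$sfrag) && !is.na(ds$sfrag[j]) && ds$sfrag[j] == i)
      keep <- c(keep, i)
  }
  keep
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$below_detection) {
    cat("ANI: below detection (no retained fragment pairs)\n")
  } else {
    cat(sprintf("ANI: %.2f%% over %d reciprocal fragment(s) of %d nt\n",
                x$ani, x$n_fragments_used, x$fragment_len))
  }
  invisible(x)
}
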