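# The whole-genome RBH-coverage distance:
#   D(A,B) = 1 - (C_AB + C_BA) / (L_A + L_B)
# where C_AB is the length of genome A covered by ORFs with reciprocal best
# hits in genome B.

#' Genome distance from an RBH coverage result
#'
#' @param cov Coverage list from [rbh_coverage()] (fields `c_ab`, `c_ba`,
#'   `l_a`, `l_b`).
#' @return Distance in `[0, 1]`.
#' @export
genome_distance <- function(cov) {
  if (cov$l_a <= 0 || cov$l_b <= 0) stop("zero genome length")
  d <- 1 - (cov$c_ab + cov$c_ba) / (cov$l_a + cov$l_b)
  min(max(d, 0), 1)
}

#' Pairwise genome distance matrix
#'
#' Runs [reciprocal_best_hits()] and [rbh_coverage()] for every unordered
#' genome pair and assembles the symmetric distance matrix. The diagonal is 0
#' by definition (the formula applied to a self-pair would measure the
#' intergenic fraction instead).
#'
#' @param genomes Named [Biostrings::DNAStringSet] (>= 2 genomes, unique
#'   ids).
#' @param orf_sets ORF table from [find_orfs()] covering all genomes.
#' @param min_query_cov,max_evalue,seed_k,seed_min Passed to
#'   [reciprocal_best_hits()].
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
distance_matrix <- function(genomes, orf_sets, min_query_cov = 0.5,
                            max_evalue = 1e-4, seed_k = 4, seed_min = 2) {
  ids <- names(genomes)
  if (length(ids) < 2) stop("need at least 2 genomes")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  by_genome <- split(orf_sets, factor(orf_sets$genome_id, levels = ids))
  lens <- Biostrings::width(genomes)
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      rbh <- reciprocal_best_hits(by_genome[[i]], by_genome[[j]],
                                  min_query_cov = min_query_cov,
                                  max_evalue = max_evalue,
                                  seed_k = seed_k, seed_min = seed_min)
      cov <- rbh_coverage(rbh, by_genome[[i]], by_genome[[j]],
                          lens[i], lens[j])
      d[i, j] <- d[j, i] <- genome_distance(cov)
    }
  }
  d
}
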