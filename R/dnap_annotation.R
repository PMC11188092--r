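# Assignment of DNAP family and in-family clade to predicted proteins by
# best hit against a labelled reference set, plus catalytic-residue
# screening through the pairwise alignment to the best reference.

.dnap_families <- c("A", "B", "C", "divA1", "divA2")

#' Assign a DNAP family and clade to one protein
#'
#' The protein is aligned to every labelled reference; the best hit by bit
#' score with E-value at or below `max_evalue` determines family and clade
#' (ties broken by the lexicographically smaller reference id). Without a
#' qualifying hit the family is `"none"`.
#'
#' @param protein Protein sequence (character or `AAString`).
#' @param refs Named [Biostrings::AAStringSet] of reference DNAPs.
#' @param labels Data frame with columns `ref_id`, `family`, `clade`.
#' @param max_evalue E-value threshold (default 1e-4).
#' @return One-row data frame: `family`, `clade`, `best_ref`, `score`,
#'   `bitscore`, `evalue`, `ref_cov`.
#' @export
assign_family <- function(protein, refs, labels, max_evalue = 1e-4) {
  stopifnot(length(refs) > 0, all(names(refs) %in% labels$ref_id))
  protein <- as.character(protein)
  space_base <- length(refs) * mean(Biostrings::width(refs))
  hits <- lapply(names(refs), function(rid) {
    al <- align_pair(protein, as.character(refs[[rid]]),
                     search_space = space_base * nchar(protein))
    al$ref_id <- rid
    al$ref_cov <- if (al$send > 0)
      (al$send - al$sstart + 1) / Biostrings::width(refs)[match(rid, names(refs))]
    else 0
    al
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$bitscore, hits$ref_id), , drop = FALSE]
  best <- hits[1, ]
  if (best$evalue > max_evalue) {
    return(data.frame(family = "none", clade = NA_character_,
                      best_ref = NA_character_, score = NA_real_,
                      bitscore = NA_real_, evalue = NA_real_,
                      ref_cov = NA_real_, stringsAsFactors = FALSE))
  }
  lab <- labels[labels$ref_id == best$ref_id, , drop = FALSE]
  data.frame(family = lab$family[1], clade = lab$clade[1],
             best_ref = best$ref_id, score = best$score,
             bitscore = best$bitscore, evalue = best$evalue,
             ref_cov = best$ref_cov, stringsAsFactors = FALSE)
}

#' Annotate every ORF of one or more genomes against DNAP references
#'
#' Batch version of [assign_family()]. With `seed_k > 0` only proteins
#' sharing at least `seed_min` k-mers with a reference are aligned (the
#' others cannot produce a qualifying hit); hits are reported one row per
#' protein with a qualifying best hit.
#'
#' @param orfs ORF table from [find_orfs()] (any number of genomes).
#' @param refs Named [Biostrings::AAStringSet] of references.
#' @param labels Reference label table (`ref_id`, `family`, `clade`).
#' @param max_evalue E-value threshold (default 1e-4).
#' @param seed_k,seed_min Seeding prefilter (see [reciprocal_best_hits()]);
#'   `seed_k = 0` aligns every protein to every reference.
#' @return Data frame of calls: `protein_id`, `genome_id`, `family`,
#'   `clade`, `best_ref`, `score`, `bitscore`, `evalue`, `ref_cov`.
#' @export
annotate_orfs <- function(orfs, refs, labels, max_evalue = 1e-4,
                          seed_k = 4, seed_min = 2) {
  empty <- data.frame(protein_id = character(), genome_id = character(),
                      family = character(), clade = character(),
                      best_ref = character(), score = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      ref_cov = numeric(), stringsAsFactors = FALSE)
  if (nrow(orfs) == 0) return(empty)
  mat <- .blosum62()
  enc_q <- .encode_seqs(orfs$protein, rownames(mat))
  enc_r <- .encode_seqs(as.character(refs), rownames(mat))
  rlens <- Biostrings::width(refs)
  if (seed_k > 0) {
    counts <- .shared_kmer_counts(.kmer_keys(orfs$protein, seed_k),
                                  .kmer_keys(as.character(refs), seed_k))
    cand <- which(counts >= seed_min, arr.ind = TRUE)
  } else {
    cand <- as.matrix(expand.grid(row = seq_len(nrow(orfs)),
                                  col = seq_along(refs)))
  }
  if (nrow(cand) == 0) return(empty)
  scores <- .sw_pair_scores(enc_q, enc_r, cand)
  space_base <- length(refs) * mean(rlens)
  rows <- list()
  for (qi in unique(cand[, 1])) {
    sel <- cand[, 1] == qi
    ris <- cand[sel, 2]
    sc <- scores[sel]
    ord <- order(-sc, names(refs)[ris])
    ri <- ris[ord[1]]
    bits <- bit_score(sc[ord[1]])
    ev <- evalue_from_bits(bits, space_base * nchar(orfs$protein[qi]))
    if (ev > max_evalue) next
    al <- .sw_full(enc_q[[qi]], enc_r[[ri]], mat, 11, 1)
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = orfs$orf_id[qi], genome_id = orfs$genome_id[qi],
      family = labels$family[match(names(refs)[ri], labels$ref_id)],
      clade = labels$clade[match(names(refs)[ri], labels$ref_id)],
      best_ref = names(refs)[ri], score = al$score, bitscore = bits,
      evalue = ev,
      ref_cov = if (al$length > 0) (al$send - al$sstart + 1) / rlens[ri] else 0,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$genome_id, out$protein_id), , drop = FALSE]
}

#' Screen catalytic motif residues through the best-reference alignment
#'
#' The protein is aligned to its best reference; for every motif position the
#' aligned query residue is read off. A motif is `intact` when all its
#' positions carry an allowed residue, `absent` when any position falls in a
#' gap or outside the aligned span, and `degraded` otherwise.
#'
#' @param protein Protein sequence.
#' @param call A call row from [assign_family()] / [annotate_orfs()]
#'   (family must not be `"none"`).
#' @param refs Reference [Biostrings::AAStringSet].
#' @param motifs Motif table: `ref_id`, `motif`, `position` (1-based in the
#'   reference), `residues` (string of allowed residues, e.g. `"D"` or
#'   `"DE"`).
#' @return Data frame: `motif`, `status` for each motif defined on the best
#'   reference.
#' @export
check_catalytic <- function(protein, call, refs, motifs) {
  if (call$family == "none") stop("no family call for this protein")
  rid <- call$best_ref
  mset <- motifs[motifs$ref_id == rid, , drop = FALSE]
  if (nrow(mset) == 0)
    return(data.frame(motif = character(), status = character(),
                      stringsAsFactors = FALSE))
  al <- align_pair(protein, as.character(refs[[rid]]), details = TRUE)
  cols <- attr(al, "columns")
  # reference position -> query position (NA if gapped or unaligned)
  ref_to_query <- rep(NA_integer_, Biostrings::width(refs)[match(rid, names(refs))])
  aligned <- cols["s", ] > 0
  ref_to_query[cols["s", aligned]] <- ifelse(cols["q", aligned] > 0,
                                             cols["q", aligned], NA_integer_)
  qchars <- strsplit(as.character(protein), "", fixed = TRUE)[[1]]
  status <- vapply(unique(mset$motif), function(mo) {
    pos <- mset$position[mset$motif == mo]
    req <- mset$residues[mset$motif == mo]
    qpos <- ref_to_query[pos]
    if (any(is.na(qpos))) return("absent")
    ok <- vapply(seq_along(qpos), function(i) {
      grepl(qchars[qpos[i]], req[i], fixed = TRUE)
    }, logical(1))
    if (all(ok)) "intact" else "degraded"
  }, character(1))
  data.frame(motif = unique(mset$motif), status = unname(status),
             stringsAsFactors = FALSE)
}

#' Retain catalytically active, (near) full-length calls
#'
#' A call is kept when all its polymerase motifs (motif names starting with
#' `"Pol"`) are intact and its alignment covers at least `min_ref_cov` of
#' the reference.
#'
#' @param calls Call table from [annotate_orfs()].
#' @param proteins Named [Biostrings::AAStringSet] with the called proteins.
#' @param refs,motifs As in [check_catalytic()].
#' @param min_ref_cov Minimum reference coverage (default 0.8).
#' @param pol_prefix Prefix identifying polymerase motifs (default "Pol").
#' @return The retained subset of `calls`, with a `pol_intact` column.
#' @export
retain_active_calls <- function(calls, proteins, refs, motifs,
                                min_ref_cov = 0.8, pol_prefix = "Pol") {
  if (nrow(calls) == 0) return(cbind(calls, pol_intact = logical(0)))
  keep <- logical(nrow(calls))
  pol_ok <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    st <- check_catalytic(as.character(proteins[[calls$protein_id[i]]]),
                          calls[i, ], refs, motifs)
    pol <- st[startsWith(st$motif, pol_prefix), , drop = FALSE]
    pol_ok[i] <- nrow(pol) == 0 || all(pol$status == "intact")
    keep[i] <- pol_ok[i] && calls$ref_cov[i] >= min_ref_cov
  }
  out <- calls[keep, , drop = FALSE]
  out$pol_intact <- pol_ok[keep]
  rownames(out) <- NULL
  out
}

#' Summarize DNAP content per genome
#'
#' @param calls Call table from [annotate_orfs()] (rows are qualifying
#'   hits).
#' @param genome_ids Optional vector of all genome ids, so DNAP-free genomes
#'   appear with status `"no-DNAP"`.
#' @return Data frame: `genome_id`, `status` (`no-DNAP`, `single-DNAP`,
#'   `multi-DNAP`), `families` (comma-separated), `n_dnaps`, `state`
#'   (`family/clade` of the single call, NA otherwise).
#' @export
classify_heterogeneity <- function(calls, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- unique(calls$genome_id)
  rows <- lapply(genome_ids, function(g) {
    cc <- calls[calls$genome_id == g, , drop = FALSE]
    if (nrow(cc) == 0)
      return(data.frame(genome_id = g, status = "no-DNAP", families = "",
                        n_dnaps = 0L, state = NA_character_,
                        stringsAsFactors = FALSE))
    fams <- sort(unique(cc$family))
    status <- if (nrow(cc) == 1) "single-DNAP" else "multi-DNAP"
    state <- if (nrow(cc) == 1)
      paste0(cc$family[1], ifelse(is.na(cc$clade[1]), "",
                                  paste0("/", cc$clade[1])))
    else NA_character_
    data.frame(genome_id = g, status = status,
               families = paste(fams, collapse = ","),
               n_dnaps = nrow(cc), state = state, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
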