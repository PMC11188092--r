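# Six-frame ORF extraction. An ORF runs from an ATG through the first
# in-frame stop (stop included in the interval); ORFs strictly contained in a
# longer retained ORF on either strand are removed ("non-nested").

empty_orf_table <- function() {
  data.frame(genome_id = character(), orf_id = character(),
             start = integer(), end = integer(), strand = character(),
             frame = integer(), protein = character(),
             stringsAsFactors = FALSE)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code. For `strand = "-"` the reverse complement is
#' translated. Codons containing characters other than A/C/G/T yield `X`;
#' stop codons yield no character.
#'
#' @param nt_seq Nucleotide string (length divisible by 3).
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid string.
#' @export
translate_codons <- function(nt_seq, strand = "+") {
  nt_seq <- toupper(as.character(nt_seq))
  if (nchar(nt_seq) %% 3 != 0)
    stop("sequence length not divisible by 3")
  if (strand == "-")
    nt_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt_seq)))
  n <- nchar(nt_seq) %/% 3
  if (n == 0) return("")
  codons <- substring(nt_seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa[aa != "*"], collapse = "")
}

# 1-based start positions of ATG and stop codons in a character sequence
.codon_positions <- function(seq_chr, patterns) {
  unlist(lapply(patterns, function(p) {
    m <- gregexpr(p, seq_chr, fixed = TRUE)[[1]]
    m[m > 0]
  }), use.names = FALSE)
}

# all ATG-to-stop ORFs on the forward strand of seq_chr, 0-based half-open
.scan_forward <- function(seq_chr, min_orf_len) {
  atg <- sort(.codon_positions(seq_chr, "ATG"))
  stp <- sort(.codon_positions(seq_chr, c("TAA", "TAG", "TGA")))
  if (length(atg) == 0 || length(stp) == 0)
    return(data.frame(start = integer(), end = integer(), frame = integer()))
  out <- vector("list", 3)
  for (f in 0:2) {
    a <- atg[(atg - 1) %% 3 == f]
    s <- stp[(stp - 1) %% 3 == f]
    if (length(a) == 0 || length(s) == 0) next
    # first stop at or after each start
    idx <- findInterval(a - 1, s) + 1L
    ok <- idx <= length(s)
    a <- a[ok]; idx <- idx[ok]
    if (length(a) == 0) next
    end1 <- s[idx] + 2L          # 1-based inclusive end of stop codon
    keep <- (end1 - a + 1L) >= min_orf_len
    out[[f + 1]] <- data.frame(start = a[keep] - 1L, end = end1[keep],
                               frame = rep(f, sum(keep)))
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(data.frame(start = integer(), end = integer(),
                                   frame = integer()))))
}

# drop ORFs whose interval is strictly contained in a longer retained ORF
# (either strand); ties on length keep the lower start coordinate
.filter_nested <- function(df) {
  if (nrow(df) <= 1) return(df)
  len <- df$end - df$start
  ord <- order(-len, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  len <- len[ord]
  keep <- logical(nrow(df))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    contained <- any(ks <= s & e <= ke & !(ks == s & ke == e))
    if (!contained) {
      keep[i] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  df[keep, , drop = FALSE]
}

#' Find the non-nested ORF complement of one or more genomes
#'
#' All six reading frames are scanned. Each ORF extends from an ATG to the
#' first in-frame stop codon (TAA/TAG/TGA, included in the interval and in
#' the length threshold); ORFs shorter than `min_orf_len` nucleotides and
#' ORFs strictly nested inside a longer retained ORF on either strand are
#' discarded. Coordinates are 0-based half-open in genome coordinates;
#' `frame` is the scanned-strand frame (start offset mod 3).
#'
#' @param genomes A [Biostrings::DNAStringSet] (or single `DNAString` /
#'   character with `genome_id`).
#' @param min_orf_len Minimum ORF length in nucleotides, stop included
#'   (default 75).
#' @param genome_id Id used when `genomes` is a bare sequence.
#' @return A data frame with columns `genome_id`, `orf_id`, `start`, `end`,
#'   `strand`, `frame`, `protein`, sorted by genome and start.
#' @export
find_orfs <- function(genomes, min_orf_len = 75, genome_id = "genome") {
  if (!methods::is(genomes, "DNAStringSet")) {
    genomes <- Biostrings::DNAStringSet(setNames(as.character(genomes)[1],
                                                 genome_id))
  }
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must be uniquely named")
  res <- lapply(names(genomes), function(gid) {
    fwd_chr <- as.character(genomes[[gid]])
    L <- nchar(fwd_chr)
    rev_chr <- as.character(Biostrings::reverseComplement(genomes[[gid]]))
    plus <- .scan_forward(fwd_chr, min_orf_len)
    plus$strand <- rep("+", nrow(plus))
    minus <- .scan_forward(rev_chr, min_orf_len)
    if (nrow(minus)) {
      # map reverse-complement coordinates back to genome coordinates
      gstart <- L - minus$end
      gend <- L - minus$start
      minus$rc_start <- minus$start
      minus$start <- gstart
      minus$end <- gend
      minus$strand <- "-"
    } else minus$strand <- character(0)
    df <- rbind(plus[, c("start", "end", "strand", "frame")],
                minus[, c("start", "end", "strand", "frame")])
    df <- .filter_nested(df)
    if (nrow(df) == 0) return(empty_orf_table())
    df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
    prot <- vapply(seq_len(nrow(df)), function(i) {
      sub <- substring(fwd_chr, df$start[i] + 1, df$end[i])
      translate_codons(sub, df$strand[i])
    }, character(1))
    data.frame(genome_id = gid,
               orf_id = sprintf("%s_orf%04d", gid, seq_len(nrow(df))),
               start = df$start, end = df$end, strand = df$strand,
               frame = df$frame, protein = prot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract the proteins of an ORF table as an AAStringSet
#'
#' @param orfs ORF table from [find_orfs()].
#' @return A named [Biostrings::AAStringSet].
#' @export
orf_proteins <- function(orfs) {
  if (nrow(orfs) == 0) return(Biostrings::AAStringSet())
  Biostrings::AAStringSet(setNames(orfs$protein, orfs$orf_id))
}
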