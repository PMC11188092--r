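# Readers and writers for the external formats used by the pipeline.
# Internal coordinates are 0-based half-open; everything written to disk
# (GFF3) is 1-based inclusive.

#' Read a nucleotide FASTA file of genome records
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`. Record ids are the
#' first whitespace-delimited token of the header; the full header is kept as
#' a `description` metadata column.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  x <- validate_fasta_records(x, path)
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record ", which(bad)[1], " ('", names(x)[which(bad)[1]],
         "') in ", path, " contains non-ACGTN characters")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(x)
  S4Vectors::mcols(out)$description <- attr(x, "description")
  out
}

#' Read a protein FASTA file
#'
#' @inheritParams read_genome_fasta
#' @return A [Biostrings::AAStringSet] named by record id.
#' @export
read_protein_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  x <- validate_fasta_records(x, path)
  seqs <- toupper(as.character(x))
  bad <- grepl(paste0("[^", paste(Biostrings::AA_STANDARD, collapse = ""), "X*]"),
               seqs)
  if (any(bad))
    stop("record ", which(bad)[1], " ('", names(x)[which(bad)[1]],
         "') in ", path, " contains invalid amino-acid characters")
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(x)
  S4Vectors::mcols(out)$description <- attr(x, "description")
  out
}

validate_fasta_records <- function(x, path) {
  if (length(x) == 0) stop("no records in ", path)
  empty <- Biostrings::width(x) == 0
  if (any(empty))
    stop("record ", which(empty)[1], " in ", path, " has an empty sequence")
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  if (any(ids == ""))
    stop("record ", which(ids == "")[1], " in ", path, " has an empty header")
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop("duplicate record id '", d, "' in ", path)
  }
  names(x) <- ids
  attr(x, "description") <- desc
  x
}

#' Write sequences to FASTA
#'
#' @param x An `XStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse a Newick string into a phylogenetic tree
#'
#' @param text A Newick string (single tree, with branch lengths).
#' @return An [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(text) {
  opens <- gregexpr("(", text, fixed = TRUE)[[1]]
  closes <- gregexpr(")", text, fixed = TRUE)[[1]]
  n_open <- sum(opens > 0)
  n_close <- sum(closes > 0)
  if (n_open != n_close) {
    pos <- if (n_open > n_close) opens[n_close + 1] else closes[n_open + 1]
    stop("unbalanced parentheses in Newick string near position ", pos)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  tr
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with enough digits to round-trip.
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

#' Write an ORF set to GFF3
#'
#' Internal 0-based half-open intervals become 1-based inclusive GFF3
#' coordinates.
#'
#' @param orfs An ORF table as returned by [find_orfs()].
#' @param path Output path.
#' @export
write_gff3 <- function(orfs, path) {
  if (nrow(orfs) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$genome_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- orfs$orf_id
  S4Vectors::mcols(gr)$frame <- orfs$frame
  # ORFs always begin at a codon boundary
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read an ORF GFF3 file back into an ORF table
#'
#' @param path GFF3 path written by [write_gff3()].
#' @return A data frame with 0-based half-open `start`/`end` columns.
#' @export
read_gff3 <- function(path) {
  first <- readLines(path, n = 2)
  if (length(first) < 2 || !any(nzchar(first[-1])))
    return(empty_orf_table())
  gr <- rtracklayer::import.gff3(path)
  data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    orf_id = as.character(S4Vectors::mcols(gr)$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = as.integer(as.character(S4Vectors::mcols(gr)$frame)),
    stringsAsFactors = FALSE
  )
}

#' Write a table as tab-separated values with a header row
#'
#' @param x A data frame (or matrix with dimnames, written with a leading id
#'   column).
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with a header row
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
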