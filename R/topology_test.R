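# Constrained-vs-unconstrained topology comparison: per-site log-likelihoods
# under an F81-type protein model (Felsenstein pruning with closed-form
# transition probabilities) and the Approximately Unbiased test by
# multiscale RELL bootstrap.

.aa_order <- function() Biostrings::AA_STANDARD

#' Observed amino-acid frequencies of an alignment
#'
#' Gaps and ambiguous letters are ignored; a small pseudocount keeps every
#' frequency positive.
#'
#' @param aln Named character vector or `AAStringSet` of aligned rows.
#' @return Named 20-vector summing to 1.
#' @export
alignment_freqs <- function(aln) {
  aa <- .aa_order()
  chars <- unlist(strsplit(as.character(aln), "", fixed = TRUE))
  counts <- as.numeric(table(factor(chars, levels = aa))) + 0.5
  setNames(counts / sum(counts), aa)
}

.check_alignment <- function(aln) {
  nm <- names(aln)
  aln <- as.character(aln)
  if (is.null(names(aln))) names(aln) <- nm
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment rows must be uniquely named")
  if (length(unique(nchar(aln))) != 1)
    stop("alignment rows must have equal length")
  aln
}

#' Per-site log-likelihoods under the F81-type protein model
#'
#' Transition probabilities are `P_ij(t) = exp(-beta t) delta_ij +
#' (1 - exp(-beta t)) pi_j` with `beta = 1 / (1 - sum(pi^2))`, evaluated by
#' Felsenstein pruning. Gaps and `X` are treated as missing data (partial
#' likelihood 1 in every state). Site log-likelihoods are floored at -745
#' (the smallest representable log density) when an observed residue has
#' zero probability.
#'
#' @param aln Named aligned sequences (equal lengths; names must match the
#'   tree's tip labels).
#' @param tree Rooted or unrooted `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param freqs Amino-acid frequencies in [Biostrings::AA_STANDARD] order
#'   (default: observed frequencies of `aln`).
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_lnl <- function(aln, tree, freqs = NULL) {
  aln <- .check_alignment(aln)
  if (!setequal(names(aln), tree$tip.label))
    stop("alignment taxa and tree leaves differ")
  if (is.null(freqs)) freqs <- alignment_freqs(aln)
  if (abs(sum(freqs) - 1) > 1e-6) stop("freqs must sum to 1")
  aa <- .aa_order()
  ns <- 20L
  beta <- 1 / (1 - sum(freqs^2))
  if (!ape::is.rooted(tree)) tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  nsite <- nchar(aln[1])
  # partial likelihood arrays: ns x nsite per node
  L <- vector("list", nn)
  for (i in seq_len(n)) {
    chars <- strsplit(aln[tree$tip.label[i]], "", fixed = TRUE)[[1]]
    idx <- match(chars, aa)
    M <- matrix(0, ns, nsite)
    obs <- !is.na(idx)
    M[cbind(idx[obs], which(obs))] <- 1
    M[, !obs] <- 1  # gap / X: missing
    L[[i]] <- M
  }
  po <- .postorder(tree)
  for (e in seq_along(po$parent)) {
    p <- po$parent[e]; ch <- po$child[e]; t <- po$len[e]
    eb <- exp(-beta * t)
    # child contribution to parent state i:
    #   eb * L_child[i, ] + (1 - eb) * (pi . L_child)
    pidot <- as.numeric(freqs %*% L[[ch]])
    contrib <- eb * L[[ch]] + (1 - eb) * matrix(pidot, ns, nsite, byrow = TRUE)
    L[[p]] <- if (p > n && is.null(L[[p]])) contrib else L[[p]] * contrib
    L[ch] <- list(NULL)
  }
  root <- po$parent[length(po$parent)]
  lik <- as.numeric(freqs %*% L[[root]])
  out <- log(lik)
  pmax(out, -745)
}

#' Approximately Unbiased test from a site log-likelihood matrix
#'
#' Shimodaira's multiscale RELL bootstrap: for each scale `r`, `B`
#' replicates of `ceiling(r * n)` sites are drawn with replacement; each
#' replicate awards its best topology (ties split equally). The bootstrap
#' proportions are transformed to `z = qnorm(1 - bp)` and fitted by weighted
#' least squares to `z(r) = d * sqrt(r) + c / sqrt(r)`; the AU p-value is
#' `1 - pnorm(d - c)`.
#'
#' @param lnl Matrix of per-site log-likelihoods, sites x topologies, with
#'   column names.
#' @param scales Resampling scale factors (default 0.5 to 1.4 by 0.1).
#' @param B Replicates per scale (default 10000).
#' @param seed Random seed (required for reproducibility).
#' @return Object of class `au_result`: data frame `table` (topology, d, c,
#'   p_au), matrix `bp` (topologies x scales), plus `scales`, `B`, `seed`.
#' @export
au_test <- function(lnl, scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                    seed = 1) {
  lnl <- as.matrix(lnl)
  if (ncol(lnl) < 2) stop("need at least 2 topologies")
  if (length(unique(scales)) < 2) stop("need at least 2 distinct scales")
  if (any(!is.finite(lnl))) stop("non-finite site log-likelihoods")
  ntopo <- ncol(lnl)
  nsite <- nrow(lnl)
  if (is.null(colnames(lnl))) colnames(lnl) <- paste0("t", seq_len(ntopo))
  set.seed(seed)
  bp <- matrix(0, ntopo, length(scales),
               dimnames = list(colnames(lnl), NULL))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * nsite)
    counts <- rmultinom(B, m, rep(1 / nsite, nsite))
    sums <- crossprod(counts, lnl)      # B x ntopo
    mx <- sums == .row_max(sums)
    wins <- mx / rowSums(mx)
    bp[, si] <- colSums(wins) / B
  }
  lo <- 1 / (B + 1)
  bpc <- pmin(pmax(bp, lo), 1 - lo)
  sr <- sqrt(scales)
  tab <- lapply(seq_len(ntopo), function(ti) {
    b <- bpc[ti, ]
    if (all(bp[ti, ] <= 0)) {
      return(data.frame(topology = colnames(lnl)[ti], d = NA_real_,
                        c = NA_real_, p_au = lo, stringsAsFactors = FALSE))
    }
    if (all(bp[ti, ] >= 1)) {
      return(data.frame(topology = colnames(lnl)[ti], d = NA_real_,
                        c = NA_real_, p_au = 1 - lo, stringsAsFactors = FALSE))
    }
    z <- qnorm(1 - b)
    w <- dnorm(z)^2 * B / (b * (1 - b))  # inverse delta-method variance
    X <- cbind(d = sr, c = 1 / sr)
    fit <- stats::lm.wfit(x = X, y = z, w = w)
    d <- fit$coefficients["d"]; cc <- fit$coefficients["c"]
    data.frame(topology = colnames(lnl)[ti], d = unname(d), c = unname(cc),
               p_au = unname(min(max(1 - pnorm(d - cc), lo), 1 - lo)),
               stringsAsFactors = FALSE)
  })
  out <- list(table = do.call(rbind, tab), bp = bp, scales = scales, B = B,
              seed = seed)
  class(out) <- "au_result"
  out
}

.row_max <- function(x) {
  do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j]))
}

#' @export
print.au_result <- function(x, ...) {
  cat("Approximately Unbiased test (B =", x$B, ", scales",
      min(x$scales), "-", max(x$scales), ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Constrained-vs-unconstrained topology comparison on a marker alignment
#'
#' Builds the unconstrained NJ tree and the group-constrained NJ tree from a
#' distance matrix (by default F81-corrected distances computed from the
#' alignment itself), re-estimates the branch lengths of both topologies by
#' non-negative least squares from the same distance matrix (so equal
#' topologies get equal likelihoods), evaluates per-site log-likelihoods
#' under the F81-type protein model, and runs the AU test.
#'
#' @param aln Named aligned marker-gene sequences.
#' @param groups Named list partitioning the taxa (e.g. by DNAP family).
#' @param dm Optional distance matrix; default: F81-corrected pairwise
#'   distances from `aln`.
#' @param scales,B,seed Passed to [au_test()].
#' @return An `au_result` with topologies `unconstrained` and `constrained`,
#'   plus the two trees as attribute `"trees"`.
#' @export
compare_constrained <- function(aln, groups, dm = NULL,
                                scales = seq(0.5, 1.4, by = 0.1),
                                B = 10000, seed = 1) {
  aln <- .check_alignment(aln)
  freqs <- alignment_freqs(aln)
  if (is.null(dm)) dm <- f81_distance_matrix(aln, freqs)
  fit_lengths <- function(topo) {
    # 2-3 taxa: a single unrooted topology; closed-form NJ lengths
    if (ape::Ntip(topo) <= 3)
      return(nj_tree(dm[topo$tip.label, topo$tip.label]))
    out <- phangorn::nnls.tree(dm[topo$tip.label, topo$tip.label],
                               ape::unroot(topo), method = "unrooted")
    out$edge.length <- pmax(out$edge.length, 0)
    out
  }
  unc <- fit_lengths(nj_tree(dm))
  con_topo <- constrained_nj(dm, groups)
  # identical topologies must yield identical likelihood columns (an exact
  # tie), not solver-noise differences
  con <- if (phangorn::RF.dist(ape::unroot(con_topo),
                               ape::unroot(unc)) == 0) unc
         else fit_lengths(con_topo)
  lnl <- cbind(unconstrained = site_lnl(aln, unc, freqs),
               constrained = site_lnl(aln, con, freqs))
  res <- au_test(lnl, scales = scales, B = B, seed = seed)
  attr(res, "trees") <- list(unconstrained = unc, constrained = con)
  res
}

#' F81-corrected pairwise distances from an alignment
#'
#' `d = -b * log(1 - p / b)` with `b = 1 - sum(pi^2)` and `p` the observed
#' fraction of differing (non-missing) columns; saturated pairs are capped.
#'
#' @param aln Named aligned sequences.
#' @param freqs Frequency vector (default: observed).
#' @param max_dist Cap for saturated pairs (default 5).
#' @return Symmetric distance matrix.
#' @export
f81_distance_matrix <- function(aln, freqs = NULL, max_dist = 5) {
  aln <- .check_alignment(aln)
  if (is.null(freqs)) freqs <- alignment_freqs(aln)
  b <- 1 - sum(freqs^2)
  ids <- names(aln)
  rows <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  ok <- rows %in% c(.aa_order())
  dim(ok) <- dim(rows)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      use <- ok[i, ] & ok[j, ]
      p <- if (any(use)) mean(rows[i, use] != rows[j, use]) else 0
      dij <- if (p >= b) max_dist else min(-b * log(1 - p / b), max_dist)
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}
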