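# Genome-tree construction and manipulation: canonical neighbor joining,
# midpoint rooting, ultrametrization by proportional subtree balancing,
# depth-threshold subtree decomposition, and group-constrained NJ.
# Trees are ape "phylo" objects throughout.

.check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite values")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (is.null(rownames(dm))) stop("distance matrix must have row names")
  invisible(dm)
}

# assemble a phylo object from parent/child key pairs (leaf keys "1".."n")
.build_phylo <- function(parent, child, length, root_key, tip_labels) {
  n <- length(tip_labels)
  kids <- split(seq_along(parent), parent)
  num <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(as.character(i), i, envir = num)
  next_internal <- n
  edge <- matrix(0L, length(parent), 2)
  elen <- numeric(length(parent))
  row <- 0L
  # iterative preorder DFS so deep trees do not overflow the call stack
  stack <- list(root_key)
  next_internal <- next_internal + 1L
  assign(root_key, next_internal, envir = num)
  while (length(stack)) {
    key <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    pnum <- get(key, envir = num)
    for (ei in kids[[key]]) {
      ck <- child[ei]
      if (!is.null(kids[[ck]])) {
        next_internal <- next_internal + 1L
        assign(ck, next_internal, envir = num)
        stack[[length(stack) + 1L]] <- ck
      }
      row <- row + 1L
      edge[row, ] <- c(pnum, get(ck, envir = num))
      elen[row] <- length[ei]
    }
  }
  tr <- list(edge = edge, edge.length = elen, tip.label = tip_labels,
             Nnode = next_internal - n)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with the standard Q criterion.
#' Negative branch-length estimates are clamped to zero; ties in Q are
#' broken by the lowest (i, j) index pair in the current matrix ordering.
#' The result is unrooted (trifurcation at the last join); a 2-taxon input
#' yields a single edge split at its midpoint.
#'
#' @param dm Symmetric distance matrix with row names.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(dm) {
  .check_distance_matrix(dm)
  ids <- rownames(dm)
  n <- length(ids)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(dm[1, 2] / 2, 2),
               tip.label = ids, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  D <- unname(dm)
  keys <- as.character(seq_len(n))
  ep <- character(0); ec <- character(0); el <- numeric(0)
  next_key <- n
  while (length(keys) > 3) {
    N <- length(keys)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- D[i, j] - bi
    next_key <- next_key + 1L
    u <- as.character(next_key)
    ep <- c(ep, u, u); ec <- c(ec, keys[i], keys[j])
    el <- c(el, max(bi, 0), max(bj, 0))
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    D <- D2
    keys <- c(keys[keep], u)
  }
  # final star join of the remaining three nodes
  next_key <- next_key + 1L
  u <- as.character(next_key)
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ep <- c(ep, u, u, u); ec <- c(ec, keys)
  el <- c(el, pmax(c(b1, b2, b3), 0))
  .build_phylo(ep, ec, el, u, ids)
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) == 2) {
    tot <- sum(tree$edge.length)
    tree$edge.length <- rep(tot / 2, 2)
    return(tree)
  }
  phangorn::midpoint(tree)
}

# edge matrix in postorder together with parent/child columns
.postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(parent = tr$edge[, 1], child = tr$edge[, 2], len = tr$edge.length)
}

#' Root-to-node path lengths
#'
#' @param tree Rooted `phylo`.
#' @return Numeric vector over node numbers (tips first).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Is a rooted tree ultrametric?
#'
#' @param tree Rooted `phylo`.
#' @param tol Relative tolerance on the root-to-leaf path spread.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  if (max(d) == 0) return(TRUE)
  (max(d) - min(d)) <= tol * max(d)
}

#' Ultrametrize a rooted tree by proportional subtree balancing
#'
#' A single descent from the root: with `m(v)` the mean path length from node
#' `v` to its descendant leaves, the root is assigned height `m(root)` and
#' each child `c` of a node at height `H` with connecting branch `b` is
#' assigned height `H * m(c) / (b + m(c))` (0 for leaves, and 0 whenever
#' `b + m(c) = 0`). Branch lengths become height differences, so the output
#' is exactly ultrametric with total depth `m(root)`; topology and leaf set
#' are unchanged.
#'
#' @param tree Rooted `phylo` with non-negative branch lengths.
#' @return Ultrametric `phylo`.
#' @export
ultrametrize <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  po <- .postorder(tree)
  nl <- c(rep(1, n), rep(0, nn - n))
  s <- numeric(nn)
  for (e in seq_along(po$parent)) {
    p <- po$parent[e]; ch <- po$child[e]
    nl[p] <- nl[p] + nl[ch]
    s[p] <- s[p] + s[ch] + nl[ch] * po$len[e]
  }
  m <- s / nl
  root <- n + 1L
  H <- numeric(nn)
  H[root] <- m[root]
  # preorder: reverse of postorder edge ordering
  newlen <- tree$edge.length
  tr2 <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_along(po$parent))) {
    p <- po$parent[e]; ch <- po$child[e]; b <- po$len[e]
    H[ch] <- if (ch <= n || (b + m[ch]) == 0) 0 else H[p] * m[ch] / (b + m[ch])
    tr2$edge.length[e] <- H[p] - H[ch]
  }
  out <- ape::reorder.phylo(tr2, "cladewise")
  attr(out, "heights") <- H
  out
}

#' Node heights of an ultrametric tree
#'
#' Height is the distance from a node to its (equidistant) descendant
#' leaves.
#'
#' @param tree Rooted ultrametric `phylo`.
#' @return Numeric vector over node numbers; exact zeros at the tips.
#' @export
node_heights <- function(tree) {
  d <- node_depths(tree)
  h <- max(d[seq_len(ape::Ntip(tree))]) - d
  h[seq_len(ape::Ntip(tree))] <- 0
  pmax(h, 0)
}

#' Decompose an ultrametric tree into subtrees at a depth threshold
#'
#' Subtree roots are exactly the nodes with height at most `depth` whose
#' parent (if any) has height above `depth`; their leaf sets partition the
#' tree's leaves. Singleton subtrees are allowed.
#'
#' @param tree Rooted ultrametric `phylo`.
#' @param depth Height threshold (default 0.15).
#' @return An object of class `subtree_decomposition`: list with `depth`,
#'   `roots` (data frame: subtree_id, node, height, n_leaves), `membership`
#'   (data frame: leaf_id, subtree_id) and the node `heights` vector.
#' @export
cut_subtrees <- function(tree, depth = 0.15) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is_ultrametric_tree(tree, tol = 1e-6))
    stop("tree is not ultrametric; run ultrametrize() first")
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  is_root_node <- vapply(seq_along(h), function(v) {
    if (v == root) return(h[v] <= depth)
    h[v] <= depth && h[parent[v]] > depth
  }, logical(1))
  roots <- which(is_root_node)
  # preorder flood-fill assigning each node to its covering subtree root
  tr <- ape::reorder.phylo(tree, "cladewise")
  assign_root <- integer(n + tree$Nnode)
  if (is_root_node[root]) assign_root[root] <- root
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    assign_root[ch] <- if (is_root_node[ch]) ch else assign_root[p]
  }
  # order subtree ids by first preorder appearance
  ord <- unique(c(if (is_root_node[root]) root,
                  tr$edge[is_root_node[tr$edge[, 2]], 2]))
  st_id <- setNames(sprintf("st%03d", seq_along(ord)), ord)
  leaf_ids <- tree$tip.label
  membership <- data.frame(
    leaf_id = leaf_ids,
    subtree_id = unname(st_id[as.character(assign_root[seq_len(n)])]),
    stringsAsFactors = FALSE
  )
  nl <- table(membership$subtree_id)
  roots_df <- data.frame(subtree_id = unname(st_id[as.character(ord)]),
                         node = ord, height = h[ord],
                         n_leaves = as.integer(nl[st_id[as.character(ord)]]),
                         stringsAsFactors = FALSE)
  out <- list(depth = depth, roots = roots_df, membership = membership,
              heights = h)
  class(out) <- "subtree_decomposition"
  out
}

#' @export
print.subtree_decomposition <- function(x, ...) {
  cat("Subtree decomposition at depth", x$depth, "\n")
  cat(" ", nrow(x$roots), "subtrees over", nrow(x$membership), "leaves\n")
  invisible(x)
}

#' Group-constrained neighbor joining
#'
#' Each group is resolved internally by NJ on its distance sub-matrix; the
#' groups are then joined by NJ on the matrix of between-group mean
#' distances. Every group is monophyletic in the result.
#'
#' @param dm Symmetric distance matrix with row names.
#' @param groups Named list of taxon-id vectors partitioning the taxa.
#' @return A `phylo` tree.
#' @export
constrained_nj <- function(dm, groups) {
  .check_distance_matrix(dm)
  ids <- rownames(dm)
  if (any(lengths(groups) == 0)) stop("empty group")
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, ids))
    stop("groups must partition the taxon set")
  if (length(groups) == 1) return(nj_tree(dm))
  k <- length(groups)
  gtag <- sprintf("ZZCONSTRAINTG%03d", seq_len(k))
  B <- matrix(0, k, k, dimnames = list(gtag, gtag))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      B[a, b] <- B[b, a] <- mean(dm[groups[[a]], groups[[b]], drop = FALSE])
    }
  }
  backbone <- nj_tree(B)
  nwk <- write_newick(backbone)
  for (a in seq_len(k)) {
    g <- groups[[a]]
    rep_str <- if (length(g) == 1) {
      g
    } else {
      sub <- midpoint_root(nj_tree(dm[g, g, drop = FALSE]))
      sub("\\);$", ")", write_newick(sub))
    }
    nwk <- sub(gtag[a], rep_str, nwk, fixed = TRUE)
  }
  read_newick(nwk)
}
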