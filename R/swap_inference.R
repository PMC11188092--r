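# Detection of DNAP-heterogeneous subtrees, grouping into swap clades, and
# small-parsimony inference of the minimal set of replacement events.

#' Detect DNAP-heterogeneous subtrees
#'
#' Two kinds of heterogeneity are reported per subtree of the decomposition:
#' type "swap" (i) -- at least two genomes carrying a single DNAP each, with
#' at least two distinct families among them (requires >= 2 genomes in the
#' subtree); and type "cooccurrence" (ii) -- at least one genome carrying
#' two or more DNAPs of different families.
#'
#' @param decomp A [cut_subtrees()] decomposition of the genome tree.
#' @param summary Per-genome summary from [classify_heterogeneity()].
#'   Genomes absent from it are treated as DNAP-free.
#' @return Data frame: `subtree_id`, `type`, `families` (comma-separated),
#'   `n_genomes`, `n_dnap_genomes`.
#' @export
detect_heterogeneous_subtrees <- function(decomp, summary) {
  mem <- decomp$membership
  missing <- setdiff(mem$leaf_id, summary$genome_id)
  if (length(missing))
    message(length(missing), " genome(s) missing from DNAP calls; treated as no-DNAP")
  out <- list()
  for (st in unique(mem$subtree_id)) {
    g <- mem$leaf_id[mem$subtree_id == st]
    s <- summary[summary$genome_id %in% g, , drop = FALSE]
    singles <- s[s$status == "single-DNAP", , drop = FALSE]
    multis <- s[s$status == "multi-DNAP", , drop = FALSE]
    if (length(g) >= 2 && nrow(singles) >= 2) {
      fams <- sort(unique(singles$families))
      if (length(fams) >= 2)
        out[[length(out) + 1]] <- data.frame(
          subtree_id = st, type = "swap",
          families = paste(fams, collapse = ","),
          n_genomes = length(g),
          n_dnap_genomes = nrow(singles) + nrow(multis),
          stringsAsFactors = FALSE)
    }
    multi_het <- multis[vapply(strsplit(multis$families, ","),
                               function(f) length(unique(f)) >= 2,
                               logical(1)), , drop = FALSE]
    if (nrow(multi_het) >= 1)
      out[[length(out) + 1]] <- data.frame(
        subtree_id = st, type = "cooccurrence",
        families = paste(sort(unique(unlist(strsplit(multi_het$families, ",")))),
                         collapse = ","),
        n_genomes = length(g),
        n_dnap_genomes = nrow(singles) + nrow(multis),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(subtree_id = character(), type = character(),
                      families = character(), n_genomes = integer(),
                      n_dnap_genomes = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Group heterogeneous subtrees into DNAP-swapping clades
#'
#' From each heterogeneous subtree root the tree is ascended while (a) the
#' parent's height does not exceed `max_clade_depth` and (b) the parent's
#' other children contain at least one DNAP-encoding genome. Overlapping
#' ascents are merged into maximal clades.
#'
#' @param tree The ultrametric genome tree the decomposition was cut from.
#' @param decomp The [cut_subtrees()] decomposition.
#' @param het Heterogeneous-subtree table from
#'   [detect_heterogeneous_subtrees()].
#' @param summary Per-genome summary from [classify_heterogeneity()].
#' @param max_clade_depth Height ceiling for the ascent (default 0.45,
#'   about the total tree depth implied by a genus cut one third in).
#' @return Data frame: `clade_id`, `root_node`, `root_height`,
#'   `subtree_ids` (comma-separated), `n_genomes`.
#' @export
group_swap_clades <- function(tree, decomp, het, summary,
                              max_clade_depth = 0.45) {
  empty <- data.frame(clade_id = character(), root_node = integer(),
                      root_height = numeric(), subtree_ids = character(),
                      n_genomes = integer(), stringsAsFactors = FALSE)
  if (nrow(het) == 0) return(empty)
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  dnap_genomes <- summary$genome_id[summary$status %in%
                                      c("single-DNAP", "multi-DNAP")]
  leaves_below <- .leaves_below(tree)
  seed_sts <- unique(het$subtree_id)
  seed_nodes <- decomp$roots$node[match(seed_sts, decomp$roots$subtree_id)]
  paths <- lapply(seed_nodes, function(v) {
    path <- v
    while (v != root) {
      p <- parent[v]
      if (h[p] > max_clade_depth) break
      sibs <- tree$edge[tree$edge[, 1] == p, 2]
      sibs <- setdiff(sibs, v)
      sib_leaves <- unlist(leaves_below[sibs], use.names = FALSE)
      if (!any(tree$tip.label[sib_leaves] %in% dnap_genomes)) break
      v <- p
      path <- c(path, v)
    }
    path
  })
  # merge ascents that share a node or whose spans are nested (a clade
  # rooted above another swallows it)
  anc <- .ancestors(tree)
  comp <- seq_along(paths)
  repeat {
    changed <- FALSE
    tops <- vapply(seq_along(paths), function(a) {
      nodes <- unique(unlist(paths[comp == comp[a]]))
      nodes[which.max(h[nodes])]
    }, numeric(1))
    for (a in seq_along(paths)) {
      for (b in seq_along(paths)) {
        if (comp[a] == comp[b]) next
        overlap <- length(intersect(paths[[a]], paths[[b]])) > 0 ||
          tops[a] %in% c(anc[[tops[b]]], tops[b]) ||
          tops[b] %in% anc[[tops[a]]]
        if (overlap) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  rows <- lapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    nodes <- unique(unlist(paths[members]))
    top <- nodes[which.max(h[nodes])]
    data.frame(root_node = top, root_height = h[top],
               subtree_ids = paste(sort(seed_sts[members]), collapse = ","),
               n_genomes = length(leaves_below[[top]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$root_height, out$root_node), , drop = FALSE]
  out <- data.frame(clade_id = sprintf("clade%02d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# list over all nodes of the tip numbers below each node (tips: themselves)
.leaves_below <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  po <- .postorder(tree)
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  for (e in seq_along(po$parent)) {
    out[[po$parent[e]]] <- c(out[[po$parent[e]]], out[[po$child[e]]])
  }
  out
}

#' Minimal DNAP replacement events on a tree by Sankoff parsimony
#'
#' Leaf states are family labels, optionally composite `"family/clade"`
#' labels. State changes cost 1 by default (configurable inter-/intra-family
#' costs); the minimum-cost ancestral labeling is found by Sankoff's
#' small-parsimony recursion, with backtracking ties resolved by preferring
#' the parent's state and then lexicographic order. Events (edges whose end
#' states differ) are classified intra-family when the family parts agree
#' and the clade parts differ, inter-family otherwise.
#'
#' @param tree Rooted `phylo` (multifurcations allowed).
#' @param leaf_states Named character vector of states for the leaves.
#'   Leaves missing from it are dropped when `exclude_missing = TRUE`
#'   (default); otherwise they enter as state `"none"`.
#' @param cost_inter,cost_intra Costs of inter- and intra-family changes
#'   (defaults 1 and 1: unit cost for any change).
#' @param exclude_missing Drop unlabeled leaves instead of erroring.
#' @return List of class `swap_report`: `min_changes`, `events` (data frame:
#'   `parent`, `child`, `child_label`, `from`, `to`, `kind`), `node_states`,
#'   `tree`.
#' @export
infer_swap_events <- function(tree, leaf_states, cost_inter = 1,
                              cost_intra = 1, exclude_missing = TRUE) {
  labs <- tree$tip.label
  missing <- setdiff(labs, names(leaf_states))
  if (length(missing)) {
    if (!exclude_missing) stop("unlabeled leaves: ", paste(missing, collapse = ", "))
    if (length(missing) == length(labs)) stop("no labeled leaves")
    if (length(labs) - length(missing) < 2) {
      keep <- setdiff(labs, missing)
      out <- list(min_changes = 0,
                  events = .empty_events(), node_states = setNames(
                    leaf_states[keep], keep), tree = NULL)
      class(out) <- "swap_report"
      return(out)
    }
    tree <- ape::keep.tip(tree, setdiff(labs, missing))
  }
  states <- sort(unique(unname(leaf_states[tree$tip.label])))
  ns <- length(states)
  fam <- vapply(strsplit(states, "/", fixed = TRUE), `[`, character(1), 1)
  cost <- matrix(cost_inter, ns, ns, dimnames = list(states, states))
  for (a in seq_len(ns)) for (b in seq_len(ns))
    if (a != b && fam[a] == fam[b]) cost[a, b] <- cost_intra
  diag(cost) <- 0
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  S <- matrix(0, nn, ns)
  S[seq_len(n), ] <- Inf
  S[cbind(seq_len(n), match(leaf_states[tree$tip.label], states))] <- 0
  po <- .postorder(tree)
  for (e in seq_along(po$parent)) {
    p <- po$parent[e]; ch <- po$child[e]
    # min over child states of S[ch, t] + cost[s, t], for each parent state s
    S[p, ] <- S[p, ] + apply(cost + rep(S[ch, ], each = ns), 1, min)
  }
  root <- n + 1L
  min_changes <- min(S[root, ])
  assign_state <- integer(nn)
  pick <- function(cand, parent_state) {
    if (!is.na(parent_state) && parent_state %in% cand) return(parent_state)
    sort(cand)[1]
  }
  root_cand <- states[S[root, ] == min_changes]
  assign_state[root] <- match(pick(root_cand, NA), states)
  for (e in rev(seq_along(po$parent))) {
    p <- po$parent[e]; ch <- po$child[e]
    ps <- assign_state[p]
    tot <- S[ch, ] + cost[ps, ]
    cand <- states[tot == min(tot)]
    assign_state[ch] <- match(pick(cand, states[ps]), states)
  }
  node_state <- states[assign_state]
  ev <- which(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
  events <- if (length(ev)) {
    from <- node_state[tree$edge[ev, 1]]
    to <- node_state[tree$edge[ev, 2]]
    ffrom <- vapply(strsplit(from, "/", fixed = TRUE), `[`, character(1), 1)
    fto <- vapply(strsplit(to, "/", fixed = TRUE), `[`, character(1), 1)
    data.frame(parent = tree$edge[ev, 1], child = tree$edge[ev, 2],
               child_label = ifelse(tree$edge[ev, 2] <= n,
                                    tree$tip.label[tree$edge[ev, 2]], NA),
               from = from, to = to,
               kind = ifelse(ffrom == fto, "intra-family", "inter-family"),
               stringsAsFactors = FALSE)
  } else .empty_events()
  out <- list(min_changes = unname(min_changes), events = events,
              node_states = node_state, tree = tree)
  class(out) <- "swap_report"
  out
}

.empty_events <- function() {
  data.frame(parent = integer(), child = integer(), child_label = character(),
             from = character(), to = character(), kind = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.swap_report <- function(x, ...) {
  cat("Swap report:", x$min_changes, "minimum state change(s);",
      nrow(x$events), "event(s)\n")
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
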