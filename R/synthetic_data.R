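# Synthetic phage-clade generator: Yule trees, F81-evolved proteomes with
# conserved gene order, planted DNAP swap events (dnap-only or en-bloc), and
# back-translated nucleotide genomes engineered so that every planted gene
# is recovered exactly by the ORF finder.

# average protein composition used as the ancestral/equilibrium frequency
# vector (order = AA_STANDARD)
.default_aa_freqs <- function() {
  f <- c(A = 8.3, R = 5.6, N = 4.3, D = 5.3, C = 1.4, Q = 3.9, E = 6.3,
         G = 7.1, H = 2.2, I = 5.6, L = 9.6, K = 5.9, M = 2.4, F = 4.0,
         P = 4.6, S = 6.6, T = 5.4, W = 1.2, Y = 3.0, V = 6.7)
  f <- f[Biostrings::AA_STANDARD]
  f / sum(f)
}

#' Configuration for the synthetic phage-clade generator
#'
#' Defaults describe the desk-scale study condition used throughout the
#' package: clades of 20 genomes with 30 genes in conserved order, mean
#' root-to-leaf divergence 0.25 amino-acid substitutions per site, one DNAP
#' inside a replication-gene block, and 1-3 sparse planted swap events.
#'
#' @param n_genomes Number of leaf genomes (default 20).
#' @param tree_height Root-to-leaf height in expected substitutions/site
#'   (default 0.25).
#' @param n_genes Genes per genome (default 30).
#' @param gene_len_range Protein length range in aa (default 120-300).
#' @param dnap_len DNAP protein length in aa (default 400).
#' @param intergenic_len_range Random interior length of intergenic spacers
#'   in nt (default 2-50, giving the ~90% coding density typical of tailed
#'   phages); 22-nt stop cassettes are added at both spacer ends on top of
#'   this.
#' @param dnap_pos,block_len Position of the DNAP gene and length of the
#'   replication block starting at it (defaults 12 and 4).
#' @param terl_pos Position of the TerL-role marker gene (default 3).
#' @param n_swaps Number of planted swap events, or `NULL` to draw 1-3.
#' @param swap_modes Modes sampled per event (default both `"dnap-only"`
#'   and `"en-bloc"`).
#' @param en_bloc_k Neighbors replaced together with the DNAP in en-bloc
#'   mode (default 2).
#' @param root_state Family/clade of the ancestral DNAP (default "A/A1").
#' @param freqs Amino-acid frequency vector (default: average protein
#'   composition).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 20, tree_height = 0.25, n_genes = 30,
                       gene_len_range = c(120, 300), dnap_len = 400,
                       intergenic_len_range = c(2, 50),
                       dnap_pos = min(12L, n_genes - block_len + 1L),
                       block_len = 4, terl_pos = 3,
                       n_swaps = NULL,
                       swap_modes = c("dnap-only", "en-bloc"),
                       en_bloc_k = 2, root_state = "A/A1",
                       freqs = .default_aa_freqs()) {
  stopifnot(n_genomes >= 2, n_genes >= 1, dnap_pos >= 1,
            dnap_pos + block_len - 1 <= n_genes, terl_pos != dnap_pos,
            en_bloc_k < block_len)
  roles <- rep("generic", n_genes)
  roles[dnap_pos] <- "dnap"
  if (block_len > 1)
    roles[(dnap_pos + 1):(dnap_pos + block_len - 1)] <- "replication"
  roles[terl_pos] <- "terl"
  out <- list(n_genomes = n_genomes, tree_height = tree_height,
              n_genes = n_genes, gene_len_range = gene_len_range,
              dnap_len = dnap_len,
              intergenic_len_range = intergenic_len_range,
              dnap_pos = dnap_pos, block_len = block_len,
              terl_pos = terl_pos, roles = roles, n_swaps = n_swaps,
              swap_modes = swap_modes, en_bloc_k = en_bloc_k,
              root_state = root_state, freqs = freqs)
  class(out) <- "sim_config"
  out
}

#' Sample an ultrametric clade tree
#'
#' Yule (pure-birth, unit rate) tree on `n` leaves, rescaled so the
#' root-to-leaf depth equals `height` exactly.
#'
#' @param n Number of leaves.
#' @param height Target root-to-leaf depth.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @return A rooted ultrametric `phylo` with tip labels `p01`, `p02`, ...
#' @export
sample_tree <- function(n, height, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2)
  tr <- if (n == 2) {
    t0 <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(1, 1), tip.label = c("t1", "t2"), Nnode = 1L)
    class(t0) <- "phylo"
    t0
  } else {
    ape::rphylo(n, birth = 1, death = 0)
  }
  depth <- max(node_depths(tr)[seq_len(n)])
  tr$edge.length <- tr$edge.length * (height / depth)
  tr$tip.label <- sprintf("p%02d", seq_len(n))
  tr
}

# evolve one protein along a branch under F81: each non-invariant site
# substitutes with probability 1 - exp(-beta t), drawing from freqs
.evolve_protein <- function(chars, t, freqs, beta, invariant = integer(0)) {
  p <- 1 - exp(-beta * t)
  hit <- which(runif(length(chars)) < p)
  hit <- setdiff(hit, invariant)
  if (length(hit))
    chars[hit] <- sample(names(freqs), length(hit), replace = TRUE,
                         prob = freqs)
  chars
}

.random_protein <- function(len, freqs) {
  c("M", sample(names(freqs), len - 1, replace = TRUE, prob = freqs))
}

#' Generate the labelled DNAP donor pools
#'
#' One independent random donor per family/clade state (A1, A2, B1, B2, C1;
#' mutually unrelated in sequence, so that every replacement -- including a
#' within-family clade replacement -- removes reciprocal-best-hit coverage
#' the way an unrelated-family homolog does). All donors share the same six
#' invariant catalytic motif positions (Pol-motifA/B/C and Exo-I/II/III)
#' with identical required residues, which never substitute during
#' evolution. Each donor also carries `en_bloc_k` unrelated block-partner
#' proteins for en-bloc replacements.
#'
#' @param config A [sim_config()].
#' @return List of class `donor_pools`: per `"family/clade"` state a list
#'   with `dnap` (character vector of residues), `block` (list of partner
#'   residue vectors), `family`, `clade`; plus attributes `motifs` (data
#'   frame) and `invariant` (positions).
#' @export
make_donor_pools <- function(config) {
  freqs <- config$freqs
  fams <- list(A = c("A1", "A2"), B = c("B1", "B2"), C = c("C1"))
  # invariant catalytic positions, shared by all donors
  motif_names <- c("Pol-motifA", "Pol-motifB", "Pol-motifC",
                   "Exo-I", "Exo-II", "Exo-III")
  motif_res <- c("D", "K", "D", "D", "D", "D")
  pos <- sort(sample(2:config$dnap_len, length(motif_names)))
  invariant <- c(1L, pos)
  pools <- list()
  motif_rows <- list()
  for (fam in names(fams)) {
    for (cl in fams[[fam]]) {
      d <- .random_protein(config$dnap_len, freqs)
      d[pos] <- motif_res
      block <- lapply(seq_len(config$en_bloc_k), function(k) {
        len <- .block_gene_length(config, k)
        .random_protein(len, freqs)
      })
      state <- paste0(fam, "/", cl)
      pools[[state]] <- list(dnap = d, block = block, family = fam,
                             clade = cl)
      rid <- paste0("ref_", fam, "_", cl)
      motif_rows[[state]] <- data.frame(ref_id = rid, motif = motif_names,
                                        position = pos,
                                        residues = motif_res,
                                        stringsAsFactors = FALSE)
    }
  }
  attr(pools, "motifs") <- do.call(rbind, motif_rows)
  attr(pools, "invariant") <- invariant
  class(pools) <- "donor_pools"
  pools
}

# length of the k-th replication-block partner gene (deterministic in the
# config so donors and ancestral genes agree)
.block_gene_length <- function(config, k) {
  r <- config$gene_len_range
  as.integer(round(r[1] + (r[2] - r[1]) * k / (config$en_bloc_k + 1)))
}

#' Evolve a conserved-order gene complement along a tree
#'
#' One ancestral protein per gene (i.i.d. from the configured frequency
#' vector, DNAP gene taken from the root donor), evolved site-independently
#' under the F81-type model along every branch. Gene order is identical in
#' every leaf. Position 1 (the initiator methionine) and the DNAP catalytic
#' motif positions are invariant.
#'
#' @param tree Rooted `phylo` from [sample_tree()].
#' @param config A [sim_config()].
#' @param donors Donor pools from [make_donor_pools()].
#' @return List: `node_seqs` (per node, list of gene residue vectors),
#'   `gene_lengths`, `gene_ids`, the inputs, and per-gene leaf alignments
#'   in `alignments`.
#' @export
evolve_genes <- function(tree, config, donors) {
  freqs <- config$freqs
  beta <- 1 / (1 - sum(freqs^2))
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  gene_ids <- sprintf("g%02d", seq_len(config$n_genes))
  lens <- integer(config$n_genes)
  anc <- vector("list", config$n_genes)
  bi <- 0L
  for (g in seq_len(config$n_genes)) {
    role <- config$roles[g]
    if (role == "dnap") {
      anc[[g]] <- donors[[config$root_state]]$dnap
    } else if (role == "replication") {
      bi <- bi + 1L
      len <- if (bi <= config$en_bloc_k) .block_gene_length(config, bi)
             else sample(config$gene_len_range[1]:config$gene_len_range[2], 1)
      anc[[g]] <- .random_protein(len, freqs)
    } else {
      len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1)
      anc[[g]] <- .random_protein(len, freqs)
    }
    lens[g] <- length(anc[[g]])
  }
  invariant <- attr(donors, "invariant")
  node_seqs <- vector("list", nn)
  node_seqs[[n + 1L]] <- anc
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    node_seqs[[ch]] <- lapply(seq_len(config$n_genes), function(g) {
      inv <- if (config$roles[g] == "dnap") invariant else 1L
      .evolve_protein(node_seqs[[p]][[g]], t, freqs, beta, invariant = inv)
    })
  }
  alignments <- lapply(seq_len(config$n_genes), function(g) {
    setNames(vapply(seq_len(n), function(i)
      paste(node_seqs[[i]][[g]], collapse = ""), character(1)),
      tree$tip.label)
  })
  names(alignments) <- gene_ids
  list(node_seqs = node_seqs, gene_lengths = lens, gene_ids = gene_ids,
       alignments = alignments, tree = tree, config = config,
       donors = donors)
}

#' Sample sparse swap events on a tree
#'
#' Chooses `n_swaps` edges such that no chosen edge is ancestral to another,
#' with pairwise-distinct donor target states all different from the root
#' state and at least one inter-family target (swap clades are ascertained
#' by cross-family heterogeneity, so a purely within-family event set would
#' be invisible to the family-level screen), and a mode per event.
#'
#' @param tree Rooted `phylo`.
#' @param config A [sim_config()].
#' @param donors Donor pools (supplies the available target states).
#' @return Data frame: `child` (node below the event edge), `mode`,
#'   `to_state`.
#' @export
sample_swap_events <- function(tree, config, donors) {
  n_swaps <- config$n_swaps
  if (is.null(n_swaps)) n_swaps <- sample(1:3, 1)
  states <- setdiff(names(donors), config$root_state)
  if (n_swaps > length(states))
    stop("not enough distinct donor states for ", n_swaps, " events")
  below <- .leaves_below(tree)
  anc_sets <- .ancestors(tree)
  candidates <- tree$edge[, 2]
  for (attempt in 1:200) {
    ch <- sample(candidates, n_swaps)
    nested <- FALSE
    for (a in seq_along(ch)) for (b in seq_along(ch)) {
      if (a != b && ch[a] %in% anc_sets[[ch[b]]]) nested <- TRUE
    }
    if (!nested) break
    if (attempt == 200) stop("could not sample non-nested event edges")
  }
  root_family <- strsplit(config$root_state, "/", fixed = TRUE)[[1]][1]
  fam_of <- vapply(strsplit(states, "/", fixed = TRUE), `[`, character(1), 1)
  targets <- sample(states, n_swaps)
  if (n_swaps > 0 && all(fam_of[match(targets, states)] == root_family)) {
    inter <- states[fam_of != root_family]
    targets[length(targets)] <- sample(inter, 1)
  }
  data.frame(child = ch,
             mode = sample(config$swap_modes, n_swaps, replace = TRUE),
             to_state = targets,
             stringsAsFactors = FALSE)
}

# ancestor node sets (excluding self) for every node
.ancestors <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(nn), function(v) {
    out <- integer(0)
    while (v != root && v != 0) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  })
}

#' Plant DNAP swap events into an evolved clade
#'
#' For each event the donor's DNAP (and, in en-bloc mode, its `en_bloc_k`
#' block-partner genes) is inserted at the child node of the event edge and
#' evolved down the remaining subtree; gene order and gene count are
#' unchanged everywhere.
#'
#' @param evolved Result of [evolve_genes()].
#' @param events Event table from [sample_swap_events()] (at most one event
#'   per edge; nested events are rejected).
#' @return The `evolved` list with leaf sequences replaced, plus `truth`:
#'   per-leaf `leaf_states` ("family/clade"), the event table with `from`
#'   states, and updated `alignments`.
#' @export
plant_swaps <- function(evolved, events) {
  tree <- evolved$tree
  config <- evolved$config
  donors <- evolved$donors
  freqs <- config$freqs
  beta <- 1 / (1 - sum(freqs^2))
  n <- ape::Ntip(tree)
  anc_sets <- .ancestors(tree)
  if (nrow(events)) {
    for (a in seq_len(nrow(events))) for (b in seq_len(nrow(events))) {
      if (a != b && events$child[a] %in% anc_sets[[events$child[b]]])
        stop("nested swap events are not supported")
    }
  }
  invariant <- attr(donors, "invariant")
  node_seqs <- evolved$node_seqs
  gpos <- which(config$roles == "dnap")
  block_pos <- integer(0)
  if (config$en_bloc_k > 0)
    block_pos <- gpos + seq_len(config$en_bloc_k)
  state_of <- rep(config$root_state, n + tree$Nnode)
  tr <- ape::reorder.phylo(tree, "cladewise")
  event_at <- setNames(rep(NA_integer_, n + tree$Nnode), NULL)
  event_at[events$child] <- seq_len(nrow(events))
  # preorder descent: re-evolve swapped genes below each event edge
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    ev <- event_at[ch]
    if (!is.na(ev)) {
      d <- donors[[events$to_state[ev]]]
      node_seqs[[ch]][[gpos]] <- d$dnap
      if (events$mode[ev] == "en-bloc") {
        for (k in seq_along(block_pos))
          node_seqs[[ch]][[block_pos[k]]] <- d$block[[k]]
      }
      state_of[ch] <- events$to_state[ev]
    } else {
      state_of[ch] <- state_of[p]
      if (state_of[p] != config$root_state) {
        # below an event: keep evolving the donor-derived genes
        src <- node_seqs[[p]]
        node_seqs[[ch]][[gpos]] <- .evolve_protein(src[[gpos]], t, freqs,
                                                   beta, invariant = invariant)
        for (k in seq_along(block_pos)) {
          donor_mode <- .donor_mode_above(ch, events, anc_sets)
          if (identical(donor_mode, "en-bloc"))
            node_seqs[[ch]][[block_pos[k]]] <-
              .evolve_protein(src[[block_pos[k]]], t, freqs, beta,
                              invariant = 1L)
        }
      }
    }
  }
  events$from <- vapply(events$child, function(v) {
    # state above the event edge = root state (events are non-nested)
    config$root_state
  }, character(1))
  events$to <- events$to_state
  alignments <- lapply(seq_len(config$n_genes), function(g) {
    setNames(vapply(seq_len(n), function(i)
      paste(node_seqs[[i]][[g]], collapse = ""), character(1)),
      tree$tip.label)
  })
  names(alignments) <- evolved$gene_ids
  out <- evolved
  out$node_seqs <- node_seqs
  out$alignments <- alignments
  out$truth <- list(
    leaf_states = setNames(state_of[seq_len(n)], tree$tip.label),
    events = events,
    tree = tree
  )
  out
}

.donor_mode_above <- function(v, events, anc_sets) {
  hit <- which(events$child == v | events$child %in% anc_sets[[v]])
  if (length(hit)) events$mode[hit[1]] else NA_character_
}

# spacer cassette carrying stop codons in all three frames of each strand
.stop_cassette <- function() "TAAATAAATAATTAATTAATTA"

# uniform synonymous back-translation; terminal TAA appended
.back_translate <- function(chars) {
  codons <- .codon_table()
  picks <- vapply(chars, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(picks, collapse = ""), "TAA")
}

.codon_env <- new.env(parent = emptyenv())
.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$tab <- split(names(gc), gc)
  }
  .codon_env$tab
}

#' Emit nucleotide genomes and reference files for a simulated clade
#'
#' Each protein is back-translated with uniformly random synonymous codons
#' and a terminal TAA; genes are joined by random intergenic spacers flanked
#' by 22-nt cassettes carrying stop codons in all six frames, so planted
#' genes are recovered exactly as non-nested ORFs.
#'
#' @param planted Result of [plant_swaps()] (or [evolve_genes()] for a
#'   swap-free clade).
#' @return List of class `phage_clade_sim`: `genomes`
#'   ([Biostrings::DNAStringSet]), `proteomes` (per-genome named residue
#'   strings), `refs` ([Biostrings::AAStringSet]), `labels`, `motifs`,
#'   `truth` (tree, leaf states, events, per-gene alignments, marker gene
#'   id), `config`.
#' @export
emit_genomes <- function(planted) {
  config <- planted$config
  tree <- planted$tree
  donors <- planted$donors
  n <- ape::Ntip(tree)
  cas <- .stop_cassette()
  r <- config$intergenic_len_range
  genomes <- character(n)
  proteomes <- vector("list", n)
  spacer_nt <- integer(n)
  for (i in seq_len(n)) {
    parts <- character(0)
    spacer <- function() {
      len <- sample(r[1]:r[2], 1)
      spacer_nt[i] <<- spacer_nt[i] + len + 2L * nchar(cas)
      paste0(cas, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), cas)
    }
    parts <- spacer()
    for (g in seq_len(config$n_genes)) {
      parts <- c(parts, .back_translate(planted$node_seqs[[i]][[g]]), spacer())
    }
    genomes[i] <- paste(parts, collapse = "")
    proteomes[[i]] <- setNames(
      vapply(planted$node_seqs[[i]], paste, character(1), collapse = ""),
      planted$gene_ids)
  }
  genomes <- Biostrings::DNAStringSet(setNames(genomes, tree$tip.label))
  names(proteomes) <- tree$tip.label
  refs <- Biostrings::AAStringSet(vapply(donors, function(d)
    paste(d$dnap, collapse = ""), character(1)))
  names(refs) <- paste0("ref_", gsub("/", "_", names(donors), fixed = TRUE))
  labels <- data.frame(
    ref_id = names(refs),
    family = vapply(donors, `[[`, character(1), "family"),
    clade = vapply(donors, `[[`, character(1), "clade"),
    stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  truth <- planted$truth
  if (is.null(truth))
    truth <- list(leaf_states = setNames(rep(config$root_state, n),
                                         tree$tip.label),
                  events = NULL, tree = tree)
  truth$alignments <- planted$alignments
  truth$marker_gene <- planted$gene_ids[config$terl_pos]
  truth$dnap_gene <- planted$gene_ids[config$dnap_pos]
  truth$spacer_nt <- setNames(spacer_nt, tree$tip.label)
  out <- list(genomes = genomes, proteomes = proteomes, refs = refs,
              labels = labels, motifs = attr(donors, "motifs"),
              truth = truth, config = config)
  class(out) <- "phage_clade_sim"
  out
}

#' Simulate a complete phage clade with planted DNAP swaps
#'
#' Orchestrates [sample_tree()], [make_donor_pools()], [evolve_genes()],
#' [sample_swap_events()], [plant_swaps()] and [emit_genomes()]. Fully
#' deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `phage_clade_sim` (see [emit_genomes()]).
#' @export
simulate_clade <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  tree <- sample_tree(config$n_genomes, config$tree_height)
  donors <- make_donor_pools(config)
  evolved <- evolve_genes(tree, config, donors)
  events <- sample_swap_events(tree, config, donors)
  planted <- plant_swaps(evolved, events)
  emit_genomes(planted)
}

#' @export
print.phage_clade_sim <- function(x, ...) {
  cat("Simulated phage clade:", length(x$genomes), "genomes,",
      x$config$n_genes, "genes each\n")
  ev <- x$truth$events
  cat(" planted swap events:", if (is.null(ev)) 0 else nrow(ev), "\n")
  invisible(x)
}

#' Write a simulated clade to a directory
#'
#' Emits `genomes.fna`, `refs.faa`, `labels.tsv`, `motifs.tsv`,
#' `truth_tree.nwk`, `truth_events.tsv` and `truth_states.tsv`.
#'
#' @param sim A `phage_clade_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genomes, file.path(dir, "genomes.fna"))
  write_fasta(sim$refs, file.path(dir, "refs.faa"))
  write_tsv(sim$labels, file.path(dir, "labels.tsv"))
  write_tsv(sim$motifs, file.path(dir, "motifs.tsv"))
  writeLines(write_newick(sim$truth$tree), file.path(dir, "truth_tree.nwk"))
  ev <- sim$truth$events
  if (!is.null(ev)) write_tsv(ev, file.path(dir, "truth_events.tsv"))
  write_tsv(data.frame(genome_id = names(sim$truth$leaf_states),
                       state = unname(sim$truth$leaf_states)),
            file.path(dir, "truth_states.tsv"))
  invisible(dir)
}
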