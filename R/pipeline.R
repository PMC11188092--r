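# End-to-end orchestration in the analysis order: ORFs -> RBH distances ->
# tree -> ultrametrize -> depth cut -> DNAP annotation -> swap detection
# (-> optional AU validation on a marker-gene alignment).

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis with the defaults used
#' throughout: 75 nt minimum ORF length, 50% RBH query coverage, E-value
#' 1e-4 for both the RBH search and the DNAP annotation, subtree depth 0.15,
#' swap-clade ceiling 0.45, and the AU-test resampling settings.
#'
#' @param min_orf_len,rbh_min_cov,rbh_max_evalue,annotate_max_evalue
#'   Thresholds of the ORF, RBH and annotation stages.
#' @param annotate_min_ref_cov Minimum reference coverage for a DNAP call to
#'   be retained as (near) full length (default 0.8).
#' @param subtree_depth,clade_max_depth Tree decomposition depths.
#' @param au_B,au_scales AU-test replicates and scales.
#' @param seed_k,seed_min Alignment seeding prefilter.
#' @param seed RNG seed recorded with every run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_orf_len = 75, rbh_min_cov = 0.5,
                            rbh_max_evalue = 1e-4,
                            annotate_max_evalue = 1e-4,
                            annotate_min_ref_cov = 0.8,
                            subtree_depth = 0.15, clade_max_depth = 0.45,
                            au_B = 10000, au_scales = seq(0.5, 1.4, 0.1),
                            seed_k = 4, seed_min = 2, seed = 1) {
  stopifnot(min_orf_len > 0, rbh_min_cov >= 0, rbh_min_cov <= 1,
            rbh_max_evalue > 0, annotate_max_evalue > 0,
            subtree_depth >= 0, clade_max_depth >= subtree_depth,
            au_B >= 1)
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full DNAP-swap analysis
#'
#' @param genomes Named [Biostrings::DNAStringSet] (>= 3 genomes).
#' @param refs Labelled DNAP reference proteins
#'   ([Biostrings::AAStringSet]).
#' @param labels Reference label table (`ref_id`, `family`, `clade`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, every stage result
#'   is written (TSV/Newick/GFF3) together with a run log carrying the
#'   config hash and seed.
#' @param motifs Optional catalytic-motif table (see [check_catalytic()]);
#'   when given, calls are screened with [retain_active_calls()] so that
#'   only full-length, catalytically intact DNAPs enter the swap analysis.
#'   Without it, only the reference-coverage filter applies.
#' @param marker_aln Optional named marker-gene alignment (e.g. TerL) for
#'   the constrained-topology AU validation; taxa are restricted to
#'   single-DNAP genomes grouped by family.
#' @return List with elements `orfs`, `dm`, `tree` (ultrametric, rooted),
#'   `decomp`, `calls`, `summary`, `het`, `clades`, `events` (per-clade
#'   [infer_swap_events()] reports), `events_table`, `au` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(genomes, refs, labels, config = pipeline_config(),
                         motifs = NULL, out_dir = NULL, marker_aln = NULL) {
  if (length(genomes) < 3)
    stop("pipeline stage 'tree' requires at least 3 genomes")
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must be uniquely named")
  set.seed(config$seed)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  note("run_pipeline on ", length(genomes), " genomes; config hash ",
       config_hash(config))
  orfs <- .stage("orfs", find_orfs(genomes, min_orf_len = config$min_orf_len))
  note("orfs: ", nrow(orfs), " ORFs")
  dm <- .stage("distances",
               distance_matrix(genomes, orfs,
                               min_query_cov = config$rbh_min_cov,
                               max_evalue = config$rbh_max_evalue,
                               seed_k = config$seed_k,
                               seed_min = config$seed_min))
  tr <- .stage("tree", {
    ultrametrize(midpoint_root(nj_tree(dm)))
  })
  note("tree: depth ", format(max(node_heights(tr)), digits = 4))
  decomp <- .stage("cut", cut_subtrees(tr, depth = config$subtree_depth))
  note("cut: ", nrow(decomp$roots), " subtrees at depth ",
       config$subtree_depth)
  calls <- .stage("annotate",
                  annotate_orfs(orfs, refs, labels,
                                max_evalue = config$annotate_max_evalue,
                                seed_k = config$seed_k,
                                seed_min = config$seed_min))
  calls <- .stage("annotate", {
    if (!is.null(motifs) && nrow(calls)) {
      prots <- Biostrings::AAStringSet(setNames(
        orfs$protein[match(calls$protein_id, orfs$orf_id)],
        calls$protein_id))
      retain_active_calls(calls, prots, refs, motifs,
                          min_ref_cov = config$annotate_min_ref_cov)
    } else {
      calls[calls$ref_cov >= config$annotate_min_ref_cov, , drop = FALSE]
    }
  })
  summary <- .stage("annotate",
                    classify_heterogeneity(calls, names(genomes)))
  note("annotate: ", nrow(calls), " DNAP calls in ",
       sum(summary$status != "no-DNAP"), " genomes")
  het <- .stage("detect-swaps", detect_heterogeneous_subtrees(decomp, summary))
  clades <- .stage("detect-swaps",
                   group_swap_clades(tr, decomp, het, summary,
                                     max_clade_depth = config$clade_max_depth))
  leaf_states <- setNames(summary$state, summary$genome_id)
  leaf_states <- leaf_states[!is.na(leaf_states)]
  events <- list()
  if (nrow(clades)) {
    for (i in seq_len(nrow(clades))) {
      sub <- if (clades$root_node[i] <= ape::Ntip(tr)) NULL
             else ape::extract.clade(tr, clades$root_node[i])
      if (is.null(sub)) next
      labelled <- intersect(sub$tip.label, names(leaf_states))
      if (length(labelled) < 2) next
      events[[clades$clade_id[i]]] <-
        .stage("detect-swaps", infer_swap_events(sub, leaf_states))
    }
  }
  events_table <- do.call(rbind, lapply(names(events), function(cid) {
    ev <- events[[cid]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(clade_id = cid, ev)
  }))
  if (is.null(events_table))
    events_table <- cbind(clade_id = character(0), .empty_events())
  note("detect-swaps: ", nrow(het), " heterogeneous subtree record(s), ",
       nrow(clades), " clade(s), ", nrow(events_table), " event(s)")
  au <- NULL
  if (!is.null(marker_aln)) {
    au <- .stage("au-test", {
      singles <- summary[summary$status == "single-DNAP", , drop = FALSE]
      taxa <- intersect(names(marker_aln), singles$genome_id)
      fams <- vapply(strsplit(singles$state[match(taxa, singles$genome_id)],
                              "/", fixed = TRUE), `[`, character(1), 1)
      if (length(unique(fams)) < 2) NULL
      else {
        groups <- split(taxa, fams)
        compare_constrained(marker_aln[taxa], groups,
                            scales = config$au_scales, B = config$au_B,
                            seed = config$seed)
      }
    })
    if (!is.null(au))
      note("au-test: constrained p_au ",
           format(au$table$p_au[au$table$topology == "constrained"],
                  digits = 4))
  }
  res <- list(orfs = orfs, dm = dm, tree = tr, decomp = decomp,
              calls = calls, summary = summary, het = het, clades = clades,
              events = events, events_table = events_table, au = au,
              config = config, log = log_lines)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, genomes, out_dir)
  res
}

#' Hash of a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character md5 hash of the serialized configuration.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[sort(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

.write_pipeline_outputs <- function(res, genomes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(res$orfs, file.path(out_dir, "orfs.gff3"))
  write_tsv(res$dm, file.path(out_dir, "dist.tsv"))
  writeLines(write_newick(res$tree), file.path(out_dir, "tree.nwk"))
  mem <- merge(res$decomp$membership,
               res$decomp$roots[, c("subtree_id", "height")],
               by = "subtree_id")[, c("leaf_id", "subtree_id", "height")]
  names(mem)[3] <- "subtree_height"
  write_tsv(mem, file.path(out_dir, "subtrees.tsv"))
  write_tsv(res$calls, file.path(out_dir, "calls.tsv"))
  write_tsv(res$summary, file.path(out_dir, "genome_summary.tsv"))
  write_tsv(res$het, file.path(out_dir, "heterogeneous_subtrees.tsv"))
  write_tsv(res$clades, file.path(out_dir, "clades.tsv"))
  write_tsv(res$events_table, file.path(out_dir, "events.tsv"))
  cfg <- res$config
  yaml::write_yaml(cfg[sort(names(cfg))], file.path(out_dir, "config.yaml"))
  writeLines(c(paste0("# polswap ",
                      as.character(utils::packageVersion("polswap")),
                      " config ", config_hash(cfg), " seed ", cfg$seed),
               res$log),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
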