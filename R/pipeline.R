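#' Run the full clustering pipeline
#'
#' End-to-end orchestration: infer one terminal-branch HGT candidate set per
#' gain/loss penalty ratio, score each set for spatial clustering over all
#' genomes, optionally score one genome's candidates for metabolic
#' clustering against a coupling network, and write a combined report.
#'
#' @param orders List of [genome_gene_order()] for all analysed genomes.
#' @param matrix A [phyletic_matrix()] with family-to-gene mapping.
#' @param tree Rooted `phylo` whose tips cover the matrix genomes.
#' @param penalty_ratios Numeric vector of P_g/P_l ratios, one candidate set
#'   each (default `c(1, 2)`, the looser and stricter conventions).
#' @param network Optional [coupling_network()] for metabolic clustering.
#' @param network_genome Genome whose candidates are scored against
#'   `network` (required with `network`; the genome with a curated metabolic
#'   reconstruction, e.g. an E. coli K12 analogue).
#' @param spatial A [spatial_config()].
#' @param metabolic A [metabolic_config()].
#' @param outdir Optional output directory; when given, the candidate sets
#'   (TSV) and the report (TSV + JSON) are written there.  Partial outputs
#'   are removed if a stage fails.
#' @param candidate_sets Optional list of precomputed [hgt_candidate_set()];
#'   skips the parsimony stage (external benchmarking mode).
#' @param verbose Log the counts (families, genes, candidates per set) and
#'   seeds via [message()].
#' @return List with `candidate_sets`, `results` (list of
#'   [clustering_result()] keyed `<set>.<statistic>`) and `report`
#'   (data.frame).
#' @export
run_pipeline <- function(orders, matrix, tree, penalty_ratios = c(1, 2),
                         network = NULL, network_genome = NULL,
                         spatial = spatial_config(),
                         metabolic = metabolic_config(),
                         outdir = NULL, candidate_sets = NULL,
                         verbose = TRUE) {
  if (!length(penalty_ratios) && is.null(candidate_sets))
    abort_validation("at least one penalty ratio is required")
  if (!is.null(network) && is.null(network_genome))
    abort_validation("network_genome must name the genome scored against the network")
  say <- function(...) if (verbose) message(sprintf(...))
  written <- character()
  on_fail_cleanup <- function() {
    for (f in written) if (file.exists(f)) unlink(f)
  }
  out <- tryCatch({
    if (is.null(candidate_sets)) {
      say("families: %d, genomes: %d, genes: %d", nrow(matrix$presence),
          ncol(matrix$presence),
          sum(vapply(orders, function(o) length(o$genes), 0L)))
      candidate_sets <- lapply(penalty_ratios, function(r)
        terminal_hgt_candidates(matrix, tree,
                                parsimony_config(gain_penalty = r,
                                                 loss_penalty = 1),
                                orders = orders))
    }
    names(candidate_sets) <- vapply(candidate_sets, function(s) s$name, "")
    results <- list()
    for (set in candidate_sets) {
      say("candidate set '%s': %d candidates (seed %d)", set$name,
          candidate_count(set), spatial$seed)
      res_sp <- spatial_analysis(orders, set, spatial)
      say("  spatial: observed %d, expected %.3f, CC %.3f, p %.4g",
          res_sp$observed, res_sp$expected, res_sp$cc, res_sp$p_value)
      results[[paste0(set$name, ".spatial")]] <- res_sp
      if (!is.null(network)) {
        genes <- set$candidates[[network_genome]]
        if (is.null(genes)) genes <- character()
        res_mb <- metabolic_analysis(network, genes, metabolic,
                                     set_name = set$name)
        say("  metabolic (%s): observed %d, expected %.3f, CC %.3f, p %.4g",
            network_genome, res_mb$observed, res_mb$expected, res_mb$cc,
            res_mb$p_value)
        results[[paste0(set$name, ".metabolic")]] <- res_mb
      }
    }
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      f1 <- file.path(outdir, "candidate_sets.tsv")
      f2 <- file.path(outdir, "report.tsv")
      f3 <- file.path(outdir, "report.json")
      written <- c(f1, f2, f3)
      write_candidate_sets(candidate_sets, f1)
      write_report(results, f2, "tsv")
      write_report(results, f3, "json")
    }
    list(candidate_sets = candidate_sets, results = results,
         report = do.call(rbind, lapply(results, as.data.frame)))
  }, error = function(e) {
    on_fail_cleanup()
    stop(e)
  })
  out
}

#' Rank candidate sets by clustering strength
#'
#' Clustering strength can benchmark HGT-detection methods: candidate sets
#' produced by different methods or parameter settings are compared by their
#' clustering scores.  A stricter set (fewer false positives) is expected to
#' cluster more strongly — but only false-discovery rates are compared, not
#' sensitivity, so the set sizes are reported alongside as an explicit
#' caveat.
#'
#' @param results List of [clustering_result()] (at least two candidate
#'   sets), e.g. the `results` element of [run_pipeline()].
#' @return Data.frame with one row per candidate set (`set_name`, `size`,
#'   `spatial_cc`, `spatial_p`, `metabolic_cc`, `metabolic_p`), sorted by
#'   spatial clustering score, descending.
#' @export
benchmark_sets <- function(results) {
  df <- do.call(rbind, lapply(results, as.data.frame))
  sets <- unique(df$set_name)
  if (length(sets) < 2)
    abort_validation("benchmarking needs at least two candidate sets")
  rows <- lapply(sets, function(s) {
    sp <- df[df$set_name == s & df$statistic == "spatial", ]
    mb <- df[df$set_name == s & df$statistic == "metabolic", ]
    data.frame(
      set_name = s,
      size = if (nrow(sp)) sp$n_candidates[[1L]] else mb$n_candidates[[1L]],
      spatial_cc = if (nrow(sp)) sp$cc[[1L]] else NA_real_,
      spatial_p = if (nrow(sp)) sp$p_value[[1L]] else NA_real_,
      metabolic_cc = if (nrow(mb)) mb$cc[[1L]] else NA_real_,
      metabolic_p = if (nrow(mb)) mb$p_value[[1L]] else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-xtfrm(out$spatial_cc)), , drop = FALSE]
}

#' Paper-scale synthetic dataset preset
#'
#' Generates a complete synthetic input set in the regime of the real
#' analysis: a rooted tree of `n_tips` genomes, per-genome gene orders of a
#' few thousand genes, a presence/absence matrix with terminal-branch gains
#' planted in operon-like blocks, and a coupling network of 4242 genes with
#' 701 fully coupled pairs.
#'
#' @param n_tips Number of genome tips (default 21).
#' @param n_root_families Families at the root (default 2000).
#' @param terminal_gain_count Planted gains per tip (default 60).
#' @param gain_block_length Genes per insertion block (default 3).
#' @param loss_rate Per-branch family loss probability (default 0.02).
#' @param seed Integer seed.
#' @return List with `tree`, `matrix`, `orders`, `planted`, `events`,
#'   `network`, `network_genome`.
#' @export
simulate_paper_scale <- function(n_tips = 21L, n_root_families = 2000L,
                                 terminal_gain_count = 60L,
                                 gain_block_length = 3L, loss_rate = 0.02,
                                 seed = 1L) {
  set.seed(substream_seed(seed, "tree"))
  tree <- ape::rtree(n_tips, tip.label = sprintf("G%02d", seq_len(n_tips)))
  sim <- simulate_family_evolution(
    tree, n_root_families = n_root_families, loss_rate = loss_rate,
    terminal_gain_count = terminal_gain_count,
    gain_block_length = gain_block_length, singleton_fraction = 0.1,
    seed = seed)
  network_genome <- tree$tip.label[[1L]]
  # node universe = the examined genes of the network genome, as in the real
  # setting where the coupling network covers one curated reconstruction
  ng_order <- sim$orders[[match(network_genome,
                                vapply(sim$orders,
                                       function(o) o$genome_id, ""))]]
  univ <- ng_order$genes[ng_order$is_examined]
  L1 <- min(701L, floor(length(univ) * (length(univ) - 1) / 4))
  net <- simulate_coupling_network(n_pairs = L1, seed = seed, nodes = univ)
  list(tree = tree, matrix = sim$matrix, orders = sim$orders,
       planted = sim$planted, events = sim$events, network = net$network,
       network_genome = network_genome)
}
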