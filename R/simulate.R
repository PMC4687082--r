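# Synthetic-data generators with known ground truth.  Defaults emulate the
# data regime of the real analysis: tens of genome tips, a few thousand genes
# per genome, operon-sized candidate blocks inserted on terminal branches,
# and a coupling network of ~4242 genes with ~701 fully coupled pairs.

#' Simulate one genome with candidate transfers inserted in blocks
#'
#' Places non-overlapping blocks of candidate genes (block lengths drawn from
#' `block_length_dist`) at uniform positions on a linear gene order,
#' emulating co-transfer of neighbouring genes on a continuous stretch of
#' DNA.  A degenerate length-1 distribution gives independent insertions
#' (the spatial null); mass on lengths 2-4 gives operon-like blocks.  A
#' fraction of the non-candidate genes can be marked unexamined to emulate
#' singletons.
#'
#' @param n_genes Number of genes on the replicon.
#' @param n_candidates Total number of candidate genes c (exactly conserved;
#'   a final block is truncated to fit if needed).
#' @param block_length_dist Named numeric vector of probabilities; names are
#'   block lengths (default `c("1" = 1)`).
#' @param singleton_fraction Fraction of non-candidate genes flagged
#'   unexamined (default 0).
#' @param seed Integer seed (deterministic output).
#' @param genome_id,replicon_id Identifiers for the emitted order.
#' @return List with `order` (a [genome_gene_order()]) and `candidates`
#'   (character vector of the planted candidate gene ids).
#' @export
simulate_genome_blocks <- function(n_genes, n_candidates,
                                   block_length_dist = c("1" = 1),
                                   singleton_fraction = 0, seed = 1L,
                                   genome_id = "simG", replicon_id = "chr") {
  if (abs(sum(block_length_dist) - 1) > 1e-9)
    abort_validation("block length probabilities must sum to 1")
  if (n_candidates > n_genes)
    abort_validation("more candidates than genes")
  if (singleton_fraction < 0 || singleton_fraction >= 1)
    abort_validation("singleton_fraction must lie in [0, 1)")
  set.seed(substream_seed(seed, paste0("genome:", genome_id)))
  lengths_avail <- as.integer(names(block_length_dist))
  blocks <- integer()
  remaining <- n_candidates
  while (remaining > 0) {
    L <- if (length(lengths_avail) == 1L) lengths_avail else
      sample(lengths_avail, 1L, prob = block_length_dist)
    L <- min(L, remaining)  # truncate the final block so that sum == c
    blocks <- c(blocks, L)
    remaining <- remaining - L
  }
  occupied <- logical(n_genes)
  cand_idx <- integer()
  for (L in blocks) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      start <- sample.int(n_genes - L + 1L, 1L)
      span <- start:(start + L - 1L)
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        cand_idx <- c(cand_idx, span)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort_validation("blocks cannot fit: too many candidates for genome size")
  }
  genes <- sprintf("%s_g%05d", genome_id, seq_len(n_genes))
  is_examined <- rep(TRUE, n_genes)
  non_cand <- setdiff(seq_len(n_genes), cand_idx)
  n_single <- round(singleton_fraction * length(non_cand))
  if (n_single > 0)
    is_examined[sample(non_cand, n_single)] <- FALSE
  list(order = genome_gene_order(genome_id, replicon_id, genes,
                                 is_examined = is_examined),
       candidates = genes[sort(cand_idx)])
}

#' Simulate gene-family evolution on a tree with known events
#'
#' Families born at the root are lost independently with probability
#' `loss_rate` on every branch (no regain); `terminal_gain_count` new
#' families are gained on each terminal branch and are absent everywhere
#' else — the planted horizontal transfers.  Gained families are inserted
#' into the recipient genome contiguously in blocks of `gain_block_length`
#' at uniform positions; vertically inherited genes keep a shared ancestral
#' order.  Every event is recorded, so the presence/absence matrix is
#' exactly reconstructable from the log.
#'
#' @param tree Rooted `phylo` tree.
#' @param n_root_families Families present at the root.
#' @param loss_rate Per-branch, per-family loss probability.
#' @param terminal_gain_count New families gained on each terminal branch.
#' @param gain_block_length Genes per contiguous insertion block (1 =
#'   independent insertions).
#' @param singleton_fraction Fraction of vertically inherited genes flagged
#'   unexamined per tip.
#' @param internal_gain_count Optional families gained on each internal
#'   non-root branch (absent elsewhere); exercises false-negative behaviour,
#'   since only terminal gains are scored downstream.
#' @param seed Integer seed.
#' @return List with `matrix` (a [phyletic_matrix()] incl. family_to_gene),
#'   `events` (data.frame `family_id`, `branch` = child node label,
#'   `event`), `orders` (list of [genome_gene_order()], one per tip) and
#'   `planted` (named list: tip -> gained gene ids, the ground truth).
#' @export
simulate_family_evolution <- function(tree, n_root_families = 50L,
                                      loss_rate = 0.02,
                                      terminal_gain_count = 5L,
                                      gain_block_length = 1L,
                                      singleton_fraction = 0,
                                      internal_gain_count = 0L, seed = 1L) {
  if (!ape::is.rooted(tree)) abort_validation("tree must be rooted")
  if (loss_rate < 0 || loss_rate >= 1)
    abort_validation("loss_rate must lie in [0, 1)")
  set.seed(substream_seed(seed, "families"))
  ntip <- length(tree$tip.label)
  nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  root_fams <- sprintf("fam%04d", seq_len(n_root_families))
  # presence of root families at every node, filled in preorder
  pres <- matrix(FALSE, nrow = n_root_families, ncol = nodes)
  pres[, root] <- TRUE
  edge <- stats::reorder(tree, "postorder")$edge
  edge <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]  # preorder
  node_label <- c(tree$tip.label, paste0("node_", root:nodes))
  ev <- list()
  gains <- list()  # per child-node label: gained family ids
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    alive <- which(pres[, p])
    lost <- alive[stats::runif(length(alive)) < loss_rate]
    keep <- setdiff(alive, lost)
    pres[keep, ch] <- TRUE
    if (length(lost))
      ev[[length(ev) + 1L]] <- data.frame(
        family_id = root_fams[lost], branch = node_label[ch], event = "loss",
        stringsAsFactors = FALSE)
    n_gain <- if (ch <= ntip) terminal_gain_count else internal_gain_count
    if (n_gain > 0) {
      fams <- sprintf("gain_%s_%03d", node_label[ch], seq_len(n_gain))
      gains[[node_label[ch]]] <- fams
      ev[[length(ev) + 1L]] <- data.frame(
        family_id = fams, branch = node_label[ch], event = "gain",
        stringsAsFactors = FALSE)
    }
  }
  # propagate internal-branch gains down to tips
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1L] == node, 2L], desc_tips))
  }
  gain_fams <- unlist(gains, use.names = FALSE)
  all_fams <- c(root_fams, gain_fams)
  M <- matrix(0L, nrow = length(all_fams), ncol = ntip,
              dimnames = list(all_fams, tree$tip.label))
  M[seq_len(n_root_families), ] <- pres[, seq_len(ntip)] + 0L
  for (lbl in names(gains)) {
    node <- match(lbl, node_label)
    M[gains[[lbl]], desc_tips(node)] <- 1L
  }
  # tip genomes: vertical genes in shared ancestral order, gained blocks
  # inserted at uniform positions
  orders <- list()
  f2g <- list()
  planted <- stats::setNames(
    replicate(ntip, character(), simplify = FALSE), tree$tip.label)
  for (t in seq_len(ntip)) {
    tip <- tree$tip.label[t]
    set.seed(substream_seed(seed, paste0("order:", tip)))
    vert <- all_fams[M[, t] == 1L & all_fams %in% root_fams]
    gained <- all_fams[M[, t] == 1L & !(all_fams %in% root_fams)]
    seq_fams <- vert
    while (length(gained)) {
      take <- utils::head(gained, gain_block_length)
      gained <- gained[-seq_along(take)]
      at <- sample.int(length(seq_fams) + 1L, 1L) - 1L
      seq_fams <- append(seq_fams, take, after = at)
    }
    genes <- paste0(tip, "|", seq_fams)
    is_examined <- rep(TRUE, length(genes))
    vert_pos <- which(seq_fams %in% root_fams)
    n_single <- round(singleton_fraction * length(vert_pos))
    if (n_single > 0)
      is_examined[sample(vert_pos, n_single)] <- FALSE
    orders[[t]] <- genome_gene_order(tip, "chr", genes,
                                     is_examined = is_examined)
    plant <- intersect(seq_fams, gains[[tip]])
    planted[[tip]] <- paste0(tip, "|", plant)
    f2g[[t]] <- data.frame(family_id = seq_fams, genome_id = tip,
                           gene_id = genes, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(family_id = character(), branch = character(),
               event = character(), stringsAsFactors = FALSE)
  list(matrix = phyletic_matrix(M, do.call(rbind, f2g)),
       events = events, orders = orders, planted = planted)
}

#' Replay an event log into tip presence/absence
#'
#' Reconstructs, for checking, the presence/absence matrix implied by a
#' [simulate_family_evolution()] event log: root families are present
#' everywhere except below their logged losses; gained families are present
#' exactly in the tips descending from their gain branch.
#'
#' @param tree The rooted `phylo` the log was simulated on.
#' @param events Event log data.frame (`family_id`, `branch`, `event`).
#' @param root_families Character vector of families present at the root.
#' @return 0/1 matrix, families x tips.
#' @export
replay_event_log <- function(tree, events, root_families) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_label <- c(tree$tip.label,
                  paste0("node_", root:(ntip + tree$Nnode)))
  gain_fams <- unique(events$family_id[events$event == "gain"])
  fams <- c(root_families, gain_fams)
  M <- matrix(0L, length(fams), ntip, dimnames = list(fams, tree$tip.label))
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1L] == node, 2L], desc_tips))
  }
  M[root_families, ] <- 1L
  for (i in seq_len(nrow(events))) {
    node <- match(events$branch[i], node_label)
    tips <- desc_tips(node)
    M[events$family_id[i], tips] <- if (events$event[i] == "gain") 1L else 0L
  }
  M
}

#' Simulate a metabolic coupling network with optional planted enrichment
#'
#' Samples `n_pairs` distinct coupled pairs over `n_nodes` genes.  With
#' `enrichment_fraction > 0`, part of the network is laid out as disjoint
#' fully-coupled modules (cliques of `module_size` genes), and a candidate
#' set of `n_candidates` genes is drawn so that the stated fraction comes
#' from within those modules (filling whole modules first, guaranteeing
#' excess coupled pairs); the remainder is drawn uniformly from the other
#' genes.  With `enrichment_fraction = 0`, pairs and candidates are uniform,
#' matching the analytic null.
#'
#' @param n_nodes Network universe size n (default 4242).
#' @param n_pairs Number of coupled pairs L1 (default 701).
#' @param n_candidates Candidate genes to draw (0 = no candidate set).
#' @param module_size Genes per coupled module (default 4).
#' @param enrichment_fraction Fraction of candidates drawn from modules.
#' @param seed Integer seed.
#' @param nodes Optional character vector to use as the node universe (e.g.
#'   a genome's gene ids); overrides `n_nodes`.
#' @return List with `network` (a [coupling_network()]), `candidates`
#'   (character vector or `NULL`) and `n_module_candidates` (ground truth).
#' @export
simulate_coupling_network <- function(n_nodes = 4242L, n_pairs = 701L,
                                      n_candidates = 0L, module_size = 4L,
                                      enrichment_fraction = 0, seed = 1L,
                                      nodes = NULL) {
  if (!is.null(nodes)) n_nodes <- length(unique(nodes))
  max_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n_pairs > max_pairs)
    abort_validation("n_pairs exceeds the number of possible pairs")
  if (enrichment_fraction < 0 || enrichment_fraction > 1)
    abort_validation("enrichment_fraction must lie in [0, 1]")
  if (enrichment_fraction > 0 && module_size < 2)
    abort_validation("module_size must be >= 2 for enrichment")
  set.seed(substream_seed(seed, "network"))
  if (is.null(nodes)) {
    nodes <- sprintf("met%05d", seq_len(n_nodes))
  } else {
    nodes <- sample(unique(nodes))  # shuffle so module membership is random
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pairs_a <- character(); pairs_b <- character()
  n_module_cand <- 0L
  module_nodes <- character()
  if (enrichment_fraction > 0 && n_candidates > 0) {
    n_from_modules <- round(enrichment_fraction * n_candidates)
    n_modules <- ceiling(n_from_modules / module_size)
    ppm <- module_size * (module_size - 1) / 2
    if (n_modules * ppm > n_pairs)
      abort_validation("not enough pairs (L1) to build the requested modules")
    module_nodes <- nodes[seq_len(n_modules * module_size)]
    for (m in seq_len(n_modules)) {
      mem <- module_nodes[((m - 1L) * module_size + 1L):(m * module_size)]
      cmb <- utils::combn(mem, 2L)
      pairs_a <- c(pairs_a, cmb[1L, ]); pairs_b <- c(pairs_b, cmb[2L, ])
    }
    n_module_cand <- as.integer(min(n_from_modules, length(module_nodes)))
  }
  seen <- pair_key(pairs_a, pairs_b)
  while (length(pairs_a) < n_pairs) {
    need <- n_pairs - length(pairs_a)
    i <- nodes[sample.int(n_nodes, need, replace = TRUE)]
    j <- nodes[sample.int(n_nodes, need, replace = TRUE)]
    ok <- i != j & !(pair_key(i, j) %in% seen) & !duplicated(pair_key(i, j))
    pairs_a <- c(pairs_a, i[ok]); pairs_b <- c(pairs_b, j[ok])
    seen <- c(seen, pair_key(i[ok], j[ok]))
  }
  network <- coupling_network(nodes, data.frame(gene_a = pairs_a,
                                                gene_b = pairs_b))
  candidates <- NULL
  if (n_candidates > 0) {
    from_mod <- utils::head(module_nodes, n_module_cand)
    rest <- setdiff(nodes, from_mod)
    candidates <- c(from_mod,
                    rest[sample.int(length(rest), n_candidates -
                                      length(from_mod))])
  }
  list(network = network, candidates = candidates,
       n_module_candidates = n_module_cand)
}
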