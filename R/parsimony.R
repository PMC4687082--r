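#' Configuration for generalized-parsimony gain/loss inference
#'
#' A gene gain (state 0 -> 1) on a branch costs `gain_penalty` (P_g), a loss
#' (1 -> 0) costs `loss_penalty` (P_l); retaining the state is free.  The two
#' standard settings are P_g/P_l = 1 (gains and losses balance, as expected
#' if genome sizes are roughly constant over time: the looser candidate set)
#' and P_g/P_l = 2 (gains doubly penalized: the stricter set).  Both root
#' states are free — presence at the root is ancestral, not a gain.
#'
#' @param gain_penalty Positive cost P_g of a 0 -> 1 transition.
#' @param loss_penalty Positive cost P_l of a 1 -> 0 transition.
#' @return An object of class `parsimony_config`.
#' @export
parsimony_config <- function(gain_penalty = 1, loss_penalty = 1) {
  if (!is.numeric(gain_penalty) || gain_penalty <= 0 ||
      !is.numeric(loss_penalty) || loss_penalty <= 0)
    abort_validation("gain and loss penalties must be positive")
  structure(list(gain_penalty = as.numeric(gain_penalty),
                 loss_penalty = as.numeric(loss_penalty)),
            class = "parsimony_config")
}

# Shared machinery: validate the tree/pattern and compute the Sankoff
# bottom-up cost tables.  Returns the 2 x (Ntip + Nnode) matrix S where
# S[s+1, v] is the minimal cost of the subtree rooted at v given state s at
# v, plus the postorder edge matrix used for the downward pass.
sankoff_tables <- function(tree, pattern, config) {
  if (!inherits(tree, "phylo")) abort_validation("tree must be a phylo object")
  if (!ape::is.rooted(tree))
    abort_validation("tree must be rooted: gain/loss asymmetry makes the root position material")
  ntip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(pattern))
  if (length(missing_tips))
    abort_validation(sprintf("tip missing from pattern: %s",
                             paste(utils::head(missing_tips, 3), collapse = ", ")))
  states <- pattern[tree$tip.label]
  if (!all(states %in% c(0, 1)))
    abort_validation("tip states must be 0 or 1")
  nnode <- tree$Nnode
  S <- matrix(0, nrow = 2L, ncol = ntip + nnode)
  S[1L, seq_len(ntip)] <- ifelse(states == 0, 0, Inf)
  S[2L, seq_len(ntip)] <- ifelse(states == 1, 0, Inf)
  edge <- stats::reorder(tree, "postorder")$edge
  pg <- config$gain_penalty
  pl <- config$loss_penalty
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    S[1L, p] <- S[1L, p] + min(S[1L, ch], pg + S[2L, ch])
    S[2L, p] <- S[2L, p] + min(pl + S[1L, ch], S[2L, ch])
  }
  list(S = S, edge = edge, ntip = ntip, root = ntip + 1L, states = states)
}

#' Minimal gain/loss cost of a phyletic pattern on a tree
#'
#' Sankoff generalized parsimony for a binary character: the minimum, over
#' all assignments of presence/absence to ancestral nodes, of the summed
#' branch transition costs (gain = P_g, loss = P_l, no change = 0).  Both
#' root states are free.
#'
#' @param tree Rooted `phylo` tree (multifurcations allowed).
#' @param pattern Named 0/1 vector of tip states; names must cover all tips.
#' @param config A [parsimony_config()].
#' @return The minimal total cost (single number).
#' @export
sankoff_min_cost <- function(tree, pattern, config = parsimony_config()) {
  tb <- sankoff_tables(tree, pattern, config)
  min(tb$S[, tb$root])
}

#' Minimum-cost event reconstruction with DELTRAN resolution
#'
#' Among all minimum-cost reconstructions, picks the one that delays state
#' changes tipward (DELTRAN): the downward pass assigns each ambiguous node
#' the parent's state, and a root tie between presence and absence is broken
#' toward absence so that gains are pushed onto the most tipward branches.
#'
#' @inheritParams sankoff_min_cost
#' @param family_id Optional label carried through to the result.
#' @return An object of class `event_reconstruction`: list with `family_id`,
#'   `events` (data.frame `parent`, `child`, `is_terminal`, `label`, `event`
#'   with event in gain/loss/none), `ancestral_states` (0/1 per node index)
#'   and `total_cost`.
#' @export
reconstruct_deltran <- function(tree, pattern, config = parsimony_config(),
                                family_id = NA_character_) {
  tb <- sankoff_tables(tree, pattern, config)
  S <- tb$S; ntip <- tb$ntip
  pg <- config$gain_penalty; pl <- config$loss_penalty
  nodes <- ntip + tree$Nnode
  state <- integer(nodes)
  state[seq_len(ntip)] <- as.integer(tb$states)
  # root: strict minimum, ties broken toward absence (state 0)
  state[tb$root] <- if (S[1L, tb$root] <= S[2L, tb$root]) 0L else 1L
  # preorder = reversed postorder; parent states are set before children
  edge <- tb$edge[rev(seq_len(nrow(tb$edge))), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    if (ch <= ntip) next
    sp <- state[p]
    cost0 <- (if (sp == 1L) pl else 0) + S[1L, ch]
    cost1 <- (if (sp == 0L) pg else 0) + S[2L, ch]
    state[ch] <- if (cost0 == cost1) sp else if (cost0 < cost1) 0L else 1L
  }
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  ev <- ifelse(state[parent] == state[child], "none",
               ifelse(state[child] == 1L, "gain", "loss"))
  labels <- ifelse(child <= ntip, tree$tip.label[child],
                   paste0("node_", child))
  events <- data.frame(parent = parent, child = child,
                       is_terminal = child <= ntip, label = labels,
                       event = ev, stringsAsFactors = FALSE)
  total <- sum((ev == "gain") * pg + (ev == "loss") * pl)
  structure(list(family_id = family_id, events = events,
                 ancestral_states = state, total_cost = total),
            class = "event_reconstruction")
}

#' @export
print.event_reconstruction <- function(x, ...) {
  cat(sprintf("<event_reconstruction> %s: %d gains, %d losses, cost %s\n",
              x$family_id, sum(x$events$event == "gain"),
              sum(x$events$event == "loss"), format(x$total_cost)))
  invisible(x)
}

#' Terminal-branch HGT candidates from a presence/absence matrix
#'
#' Runs [reconstruct_deltran()] for every gene family and collects, for each
#' genome, the genes whose family was gained on that genome's terminal branch
#' — the most recent, most reliably inferred transfers.  Genes flagged as
#' unexamined in their gene order (singletons, i.e. genes with no detected
#' ortholog in any other analysed genome) and genes on plasmid replicons are
#' conservatively never labelled as transferred.
#'
#' Tree tips without a matrix column (e.g. outgroups kept for rooting) are
#' treated as lacking every family (state 0); candidates are only emitted for
#' genomes present in the matrix.
#'
#' @param matrix A [phyletic_matrix()] with a `family_to_gene` map.
#' @param tree Rooted `phylo`; tips must be a superset of the matrix genomes.
#' @param config A [parsimony_config()].
#' @param orders Optional list of [genome_gene_order()]; when supplied,
#'   candidate genes must exist in their genome's order, and unexamined or
#'   plasmid-borne genes are dropped.
#' @param name Label for the resulting set (default `terminal.pen<ratio>`).
#' @return An [hgt_candidate_set()] with one (possibly empty) entry per
#'   matrix genome.
#' @export
terminal_hgt_candidates <- function(matrix, tree,
                                    config = parsimony_config(),
                                    orders = NULL, name = NULL) {
  pres <- matrix$presence
  genomes <- colnames(pres)
  extra_tips <- setdiff(genomes, tree$tip.label)
  if (length(extra_tips))
    abort_validation(sprintf("matrix genome not in tree: %s", extra_tips[[1L]]))
  if (is.null(name))
    name <- sprintf("terminal.pen%g", config$gain_penalty / config$loss_penalty)

  gene_index <- NULL
  if (!is.null(orders)) {
    gene_index <- do.call(rbind, lapply(orders, function(o)
      data.frame(genome_id = o$genome_id, gene_id = o$genes,
                 is_examined = o$is_examined, is_plasmid = o$is_plasmid,
                 stringsAsFactors = FALSE)))
  }

  candidates <- stats::setNames(
    replicate(length(genomes), character(), simplify = FALSE), genomes)

  # families sharing a phyletic pattern share a reconstruction
  full <- matrix(0L, nrow = nrow(pres), ncol = length(tree$tip.label),
                 dimnames = list(rownames(pres), tree$tip.label))
  full[, genomes] <- pres
  pat_key <- apply(full, 1L, paste, collapse = "")
  for (key in unique(pat_key)) {
    fams <- rownames(pres)[pat_key == key]
    pattern <- full[fams[[1L]], ]
    if (!any(pattern == 1)) next
    rec <- reconstruct_deltran(tree, pattern, config)
    gained_tips <- rec$events$label[rec$events$is_terminal &
                                      rec$events$event == "gain"]
    gained_tips <- intersect(gained_tips, genomes)
    if (!length(gained_tips)) next
    for (fam in fams) {
      for (g in gained_tips) {
        gene <- family_gene(matrix, fam, g)
        if (is.na(gene))
          abort_validation(sprintf(
            "family %s present in genome %s but has no gene mapping", fam, g))
        if (!is.null(gene_index)) {
          hit <- which(gene_index$genome_id == g & gene_index$gene_id == gene)
          if (!length(hit))
            abort_validation(sprintf("mapped gene %s not found in gene order of %s",
                                     gene, g))
          if (!gene_index$is_examined[hit[[1L]]] ||
              gene_index$is_plasmid[hit[[1L]]]) next
        }
        candidates[[g]] <- c(candidates[[g]], gene)
      }
    }
  }
  hgt_candidate_set(name, candidates,
                    config$gain_penalty / config$loss_penalty)
}

#' Compare two HGT candidate sets
#'
#' Benchmark helper: per-genome and total sizes, overlap and set differences
#' of two candidate sets defined over the same genomes.
#'
#' @param a,b [hgt_candidate_set()] objects over the same genome universe.
#' @return List with `per_genome` (data.frame: genome, n_a, n_b,
#'   intersection, a_only, b_only) and `total` (named vector: n_a, n_b,
#'   intersection, union, a_only, b_only).
#' @export
compare_candidate_sets <- function(a, b) {
  ga <- sort(names(a$candidates)); gb <- sort(names(b$candidates))
  if (!identical(ga, gb))
    abort_validation("candidate sets cover different genome universes")
  per <- do.call(rbind, lapply(ga, function(g) {
    sa <- a$candidates[[g]]; sb <- b$candidates[[g]]
    data.frame(genome = g, n_a = length(sa), n_b = length(sb),
               intersection = length(intersect(sa, sb)),
               a_only = length(setdiff(sa, sb)),
               b_only = length(setdiff(sb, sa)), stringsAsFactors = FALSE)
  }))
  total <- c(n_a = sum(per$n_a), n_b = sum(per$n_b),
             intersection = sum(per$intersection),
             union = sum(per$n_a) + sum(per$n_b) - sum(per$intersection),
             a_only = sum(per$a_only), b_only = sum(per$b_only))
  list(per_genome = per, total = total)
}
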