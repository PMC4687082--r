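#' Configuration for the spatial (genome-neighbourhood) clustering statistic
#'
#' Two candidate transfers count as genomic neighbours when at most
#' `window - 1` genes intervene between them; the default window of 3 (i.e.
#' at most 2 intervening genes, four genes considered at a time) stays within
#' the length of ~90% of E. coli operons and partly absorbs post-insertion
#' rearrangements.
#'
#' `gap_mode = "paper"` computes the null expectation and the randomizations
#' as if the examined genes of each genome were arranged consecutively,
#' without gaps — the conservative convention (unexamined genes create gaps
#' only in the observed count, so the expectation is biased upward and the
#' clustering score downward).  `gap_mode = "exact"` randomizes candidate
#' positions over the actual gene layout (candidates drawn only from examined
#' positions) and takes the null expectation as the mean randomized count.
#'
#' @param window Positive integer window w (default 3).
#' @param topology `"linear"` (matches the closed-form expectation) or
#'   `"circular"` (wrap-around neighbours; expectation adjusted).
#' @param gap_mode `"paper"` or `"exact"` (see above).
#' @param n_randomizations Number of randomizations R for the permutation
#'   p-value (default 999).
#' @param seed Integer seed; per-genome substreams are derived
#'   deterministically from (seed, genome id).
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(window = 3L, topology = c("linear", "circular"),
                           gap_mode = c("paper", "exact"),
                           n_randomizations = 999L, seed = 1L) {
  if (window < 1) abort_validation("window must be >= 1")
  if (n_randomizations < 1) abort_validation("n_randomizations must be >= 1")
  structure(list(window = as.integer(window),
                 topology = match.arg(topology),
                 gap_mode = match.arg(gap_mode),
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed)),
            class = "spatial_config")
}

# Neighbour-pair count from sorted candidate positions: a candidate at p_i
# qualifies iff the next candidate lies within `window` positions.  On a
# circle the successor of the last candidate is the first, n positions on.
count_from_positions <- function(pos, n, window, topology) {
  c_ <- length(pos)
  if (c_ < 2L) return(0L)
  qual <- diff(pos) <= window
  if (topology == "circular")
    qual <- c(qual, pos[1L] + n - pos[c_] <= window)
  sum(qual)
}

#' Count transferred neighbour pairs in a 0/1 flag sequence
#'
#' For a genome of n genes with transfer flags H_1..H_n, gene i contributes
#' C_i = 1 when H_i = 1 and at least one of its `window` nearest right-hand
#' neighbours is also flagged; the statistic is Count = sum(C_i).  In linear
#' mode positions beyond the end contribute nothing; in circular mode the
#' window wraps around.
#'
#' @param flags Integer/numeric vector of 0/1 transfer flags in gene order.
#' @param window Window size w (default 3).
#' @param topology `"linear"` or `"circular"`.
#' @return Non-negative integer count.
#' @export
count_neighbour_pairs <- function(flags, window = 3L,
                                  topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (length(flags) && !all(flags %in% c(0, 1)))
    abort_validation("flags must be 0/1")
  window <- min(as.integer(window), max(length(flags) - 1L, 0L))
  count_from_positions(which(flags == 1), length(flags), window, topology)
}

#' Closed-form null expectation of the neighbour-pair count
#'
#' Expected value of [count_neighbour_pairs()] when c candidate genes are
#' placed uniformly at random (without replacement) among n gene positions.
#' Decomposed by the distance d to the nearest right-hand candidate:
#' \deqn{E = \sum_{d=1}^{w} N_d \cdot \frac{c}{n} \cdot
#'   \prod_{j=1}^{d-1}\frac{n-c-j+1}{n-j} \cdot \frac{c-1}{n-d}}
#' with \eqn{N_d = n - d} eligible positions in linear mode (the paper's
#' three-term formula at w = 3) and \eqn{N_d = n} on a circle.
#'
#' @param n Total number of gene positions (examined genes in gap-free mode).
#' @param c Number of candidate genes (`0 <= c <= n`).
#' @param window Window size w.
#' @param topology `"linear"` or `"circular"`.
#' @return The expected count (0 when `c <= 1`).
#' @export
expected_neighbour_pairs <- function(n, c, window = 3L,
                                     topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (c > n) abort_validation("c must not exceed n")
  if (c < 0 || n < 0) abort_validation("n and c must be non-negative")
  if (c <= 1) return(0)
  dmax <- min(window, n - 1L)
  total <- 0
  run <- 1  # prod_{j<d} (n-c-j+1)/(n-j): P(first d-1 right neighbours clear)
  for (d in seq_len(dmax)) {
    npos <- if (topology == "linear") n - d else n
    total <- total + npos * (c / n) * run * (c - 1) / (n - d)
    run <- run * max(n - c - d + 1, 0) / (n - d)
  }
  total
}

#' Observed neighbour pairs for one replicon
#'
#' Builds the 0/1 flag sequence over the full replicon gene order — singleton
#' and other unexamined genes stay 0 but occupy positions, introducing gaps —
#' and applies [count_neighbour_pairs()].
#'
#' @param order A [genome_gene_order()].
#' @param candidates Character vector of candidate gene ids on this replicon.
#' @param config A [spatial_config()].
#' @return Non-negative integer count.
#' @export
observed_pairs_for_genome <- function(order, candidates,
                                      config = spatial_config()) {
  idx <- match(candidates, order$genes)
  if (anyNA(idx))
    abort_validation(sprintf("candidate gene not in replicon %s: %s",
                             order$replicon_id,
                             candidates[which(is.na(idx))[1L]]))
  if (any(!order$is_examined[idx]))
    abort_validation("candidate gene is flagged unexamined (singleton)")
  flags <- integer(length(order$genes))
  flags[idx] <- 1L
  count_neighbour_pairs(flags, config$window, config$topology)
}

# Per-genome layout used by spatial_analysis: replicon lengths, examined
# positions, and observed candidate positions, after dropping plasmids.
genome_layout <- function(orders, genes) {
  orders <- Filter(function(o) !o$is_plasmid, orders)
  if (!length(orders))
    abort_validation("candidate genome has no (non-plasmid) gene orders")
  found <- unlist(lapply(orders, function(o) intersect(genes, o$genes)))
  missing <- setdiff(genes, found)
  if (length(missing))
    abort_validation(sprintf("candidate gene not found in genome %s: %s",
                             orders[[1L]]$genome_id, missing[[1L]]))
  list(orders = orders)
}

#' Spatial clustering analysis of an HGT candidate set
#'
#' Aggregates the neighbour-pair statistic over all genomes of a candidate
#' set: the observed count sums [observed_pairs_for_genome()] over every
#' (non-plasmid) replicon; the null expectation sums
#' [expected_neighbour_pairs()] per genome; and the one-sided permutation
#' p-value redistributes each genome's candidate count uniformly without
#' replacement `n_randomizations` times, comparing the randomized total
#' against the observed total: p = (r + 1)/(R + 1).
#'
#' Permutation runs over exactly the genomes present in the candidate set's
#' universe (genomes with zero candidates contribute nothing).  With several
#' replicons per genome, gap-free mode concatenates the genome's examined
#' genes into one sequence, and exact mode samples positions over the actual
#' per-replicon layouts.
#'
#' @param orders List of [genome_gene_order()] covering the candidate
#'   genomes.
#' @param candidates An [hgt_candidate_set()] (or named list genome ->
#'   genes).
#' @param config A [spatial_config()].
#' @return A [clustering_result()] with `statistic = "spatial"`.
#' @export
spatial_analysis <- function(orders, candidates, config = spatial_config()) {
  if (inherits(candidates, "hgt_candidate_set")) {
    set_name <- candidates$name
    cand <- candidates$candidates
  } else {
    set_name <- "candidates"
    cand <- candidates
  }
  genomes <- sort(names(cand))
  w <- config$window
  topo <- config$topology
  R <- config$n_randomizations
  by_genome <- split(orders, vapply(orders, function(o) o$genome_id, ""))
  observed <- 0L
  expected <- 0
  rand_total <- numeric(R)
  for (g in genomes) {
    genes <- cand[[g]]
    if (!length(genes) && is.null(by_genome[[g]])) next
    if (is.null(by_genome[[g]]))
      abort_validation(sprintf("no gene orders for candidate genome %s", g))
    lay <- genome_layout(by_genome[[g]], genes)
    obs_g <- sum(vapply(lay$orders, function(o)
      observed_pairs_for_genome(o, intersect(genes, o$genes), config), 0L))
    observed <- observed + obs_g
    c_g <- length(genes)
    n_exam <- vapply(lay$orders, function(o) sum(o$is_examined), 0L)
    set.seed(substream_seed(config$seed, g))
    if (config$gap_mode == "paper") {
      n_g <- sum(n_exam)
      expected <- expected + expected_neighbour_pairs(n_g, c_g, w, topo)
      if (c_g >= 2)
        for (k in seq_len(R))
          rand_total[k] <- rand_total[k] +
            count_from_positions(sort(sample.int(n_g, c_g)), n_g,
                                 min(w, n_g - 1L), topo)
    } else {
      # exact: randomize over examined positions of the real layouts
      lens <- vapply(lay$orders, function(o) length(o$genes), 0L)
      repl <- rep(seq_along(lay$orders), lens)
      pos_in_repl <- unlist(lapply(lens, seq_len))
      exam <- unlist(lapply(lay$orders, function(o) o$is_examined))
      exam_idx <- which(exam)
      rand_g <- numeric(R)
      if (c_g >= 2) {
        for (k in seq_len(R)) {
          pick <- sort(exam_idx[sample.int(length(exam_idx), c_g)])
          cnt <- 0L
          for (r_i in unique(repl[pick])) {
            p <- pos_in_repl[pick[repl[pick] == r_i]]
            cnt <- cnt + count_from_positions(p, lens[r_i],
                                              min(w, lens[r_i] - 1L), topo)
          }
          rand_g[k] <- cnt
        }
      }
      expected <- expected + mean(rand_g)
      rand_total <- rand_total + rand_g
    }
  }
  r <- sum(rand_total >= observed)
  clustering_result(observed = observed, expected = expected,
                    p_value = (r + 1) / (R + 1), n_randomizations = R,
                    seed = config$seed, statistic = "spatial",
                    set_name = set_name,
                    n_candidates = sum(lengths(cand)))
}
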