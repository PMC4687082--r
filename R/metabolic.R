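#' Configuration for the metabolic (flux-coupling) clustering statistic
#'
#' The permutation null redistributes HGT status uniformly over the genes of
#' the coupling network's node universe while the topology of the
#' interaction graph stays fixed.
#'
#' @param n_randomizations Number of randomizations R (default 999).
#' @param seed Integer seed.
#' @return An object of class `metabolic_config`.
#' @export
metabolic_config <- function(n_randomizations = 999L, seed = 1L) {
  if (n_randomizations < 1) abort_validation("n_randomizations must be >= 1")
  structure(list(n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed)),
            class = "metabolic_config")
}

#' Observed fully-coupled pairs within a candidate set
#'
#' Number of coupled gene pairs with both endpoints in the candidate set.
#' Candidates outside the network's node universe are dropped with a message
#' (the null model only redistributes status within the network).
#'
#' @param network A [coupling_network()].
#' @param candidates Character vector of candidate gene ids.
#' @return Non-negative integer count.
#' @export
observed_coupled_pairs <- function(network, candidates) {
  candidates <- unique(as.character(candidates))
  outside <- setdiff(candidates, network$nodes)
  if (length(outside))
    message(sprintf("%d candidate gene(s) outside the network universe dropped",
                    length(outside)))
  inside <- setdiff(candidates, outside)
  sum(network$pairs$gene_a %in% inside & network$pairs$gene_b %in% inside)
}

#' Expected coupled pairs under the no-association null
#'
#' With n genes in the network universe and L1 fully coupled pairs, the a
#' priori probability of any pair being coupled is
#' p1 = L1 / (n (n - 1) / 2).  A candidate set of n2 genes offers
#' n2 (n2 - 1) / 2 pairs, so the null expectation is p1 * n2 (n2 - 1) / 2.
#'
#' @param n Size of the node universe (`n >= 2`).
#' @param L1 Number of coupled pairs.
#' @param n2 Number of candidate genes within the universe.
#' @return The expected count (0 when `n2 <= 1`).
#' @export
expected_coupled_pairs <- function(n, L1, n2) {
  if (n < 2) abort_validation("network universe must have at least 2 genes")
  if (n2 < 0 || n2 > n) abort_validation("n2 must lie in [0, n]")
  if (L1 < 0 || L1 > n * (n - 1) / 2)
    abort_validation("L1 must lie in [0, n(n-1)/2]")
  if (n2 <= 1) return(0)
  L1 / (n * (n - 1) / 2) * n2 * (n2 - 1) / 2
}

#' Metabolic clustering analysis of a candidate gene set
#'
#' Counts coupled pairs among the candidates, compares with the analytic
#' expectation, and computes a one-sided permutation p-value by repeatedly
#' drawing the same number of genes uniformly without replacement from the
#' node universe and recounting (edges fixed): p = (r + 1)/(R + 1).
#'
#' @param network A [coupling_network()].
#' @param candidates Character vector of candidate gene ids (e.g. one
#'   genome's entry of an [hgt_candidate_set()]).
#' @param config A [metabolic_config()].
#' @param set_name Label carried into the result.
#' @return A [clustering_result()] with `statistic = "metabolic"`.
#' @export
metabolic_analysis <- function(network, candidates,
                               config = metabolic_config(),
                               set_name = "candidates") {
  n <- length(network$nodes)
  if (n == 0) abort_validation("empty coupling network")
  candidates <- unique(as.character(candidates))
  observed <- suppressMessages(observed_coupled_pairs(network, candidates))
  inside <- intersect(candidates, network$nodes)
  n2 <- length(inside)
  if (n2 < length(candidates))
    message(sprintf("%d candidate gene(s) outside the network universe dropped",
                    length(candidates) - n2))
  expected <- expected_coupled_pairs(n, nrow(network$pairs), n2)
  R <- config$n_randomizations
  ai <- match(network$pairs$gene_a, network$nodes)
  bi <- match(network$pairs$gene_b, network$nodes)
  set.seed(substream_seed(config$seed, "metabolic"))
  rand <- integer(R)
  member <- logical(n)
  for (k in seq_len(R)) {
    member[] <- FALSE
    member[sample.int(n, n2)] <- TRUE
    rand[k] <- sum(member[ai] & member[bi])
  }
  r <- sum(rand >= observed)
  clustering_result(observed = observed, expected = expected,
                    p_value = (r + 1) / (R + 1), n_randomizations = R,
                    seed = config$seed, statistic = "metabolic",
                    set_name = set_name, n_candidates = n2)
}
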