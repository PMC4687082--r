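#' Ordered gene list for one replicon
#'
#' The basic spatial unit of the analysis: the genes of one replicon
#' (chromosome or plasmid) of one genome, in chromosomal order.  Gene order is
#' what the neighbour-pair statistic is computed on, so the order must be
#' total; positions are 0-based contiguous indices along the replicon.
#'
#' Genes flagged `is_examined = FALSE` are "singletons" (no ortholog detected
#' in any other analysed genome) or otherwise unexamined genes: they are never
#' candidate transfers, but they still occupy chromosomal positions and hence
#' introduce gaps between examined genes.
#'
#' @param genome_id Genome identifier.
#' @param replicon_id Replicon identifier (unique within the genome).
#' @param genes Character vector of gene identifiers in chromosomal order.
#' @param is_examined Logical vector, one per gene; `FALSE` marks singletons
#'   and other genes excluded from candidate status.
#' @param is_plasmid Single logical; plasmid replicons can be excluded from
#'   the analysis.
#' @return An object of class `genome_gene_order`.
#' @export
genome_gene_order <- function(genome_id, replicon_id, genes,
                              is_examined = rep(TRUE, length(genes)),
                              is_plasmid = FALSE) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    abort_validation(sprintf(
      "duplicate gene id on replicon '%s': %s", replicon_id,
      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  if (length(is_examined) != length(genes))
    abort_validation("is_examined must have one entry per gene")
  structure(
    list(genome_id = as.character(genome_id),
         replicon_id = as.character(replicon_id),
         genes = genes,
         is_examined = as.logical(is_examined),
         is_plasmid = isTRUE(as.logical(is_plasmid))),
    class = "genome_gene_order")
}

#' @export
print.genome_gene_order <- function(x, ...) {
  cat(sprintf("<genome_gene_order> %s / %s: %d genes (%d examined)%s\n",
              x$genome_id, x$replicon_id, length(x$genes),
              sum(x$is_examined), if (x$is_plasmid) " [plasmid]" else ""))
  invisible(x)
}

#' Gene-family presence/absence matrix
#'
#' Rows are orthologous gene families, columns are genomes, entries are 0/1.
#' The optional `family_to_gene` map links a (family, genome) presence to the
#' concrete gene identifier in that genome's gene order, which is needed to
#' place inferred transfers on the chromosome.
#'
#' @param presence Integer/numeric matrix of 0/1 with rownames (families) and
#'   colnames (genomes).
#' @param family_to_gene Optional data.frame with columns `family_id`,
#'   `genome_id`, `gene_id`.
#' @return An object of class `phyletic_matrix`.
#' @export
phyletic_matrix <- function(presence, family_to_gene = NULL) {
  if (!is.matrix(presence) || is.null(rownames(presence)) ||
      is.null(colnames(presence)))
    abort_validation("presence must be a matrix with family rownames and genome colnames")
  if (!all(presence %in% c(0L, 1L)))
    abort_validation(sprintf(
      "presence entries must be 0 or 1; found: %s",
      paste(utils::head(setdiff(unique(as.vector(presence)), c(0, 1)), 3),
            collapse = ", ")))
  storage.mode(presence) <- "integer"
  if (anyDuplicated(rownames(presence)))
    abort_validation("duplicate family ids")
  if (anyDuplicated(colnames(presence)))
    abort_validation("duplicate genome ids")
  if (!is.null(family_to_gene)) {
    req <- c("family_id", "genome_id", "gene_id")
    if (!all(req %in% names(family_to_gene)))
      abort_validation("family_to_gene needs columns family_id, genome_id, gene_id")
    key <- paste(family_to_gene$family_id, family_to_gene$genome_id)
    if (anyDuplicated(key))
      abort_validation("family_to_gene maps some (family, genome) twice")
    idx <- cbind(match(family_to_gene$family_id, rownames(presence)),
                 match(family_to_gene$genome_id, colnames(presence)))
    if (anyNA(idx))
      abort_validation("family_to_gene refers to unknown families or genomes")
    if (any(presence[idx] == 0L))
      abort_validation("family_to_gene maps a gene for an absent (0) entry")
  }
  structure(list(presence = presence, family_to_gene = family_to_gene),
            class = "phyletic_matrix")
}

#' @export
print.phyletic_matrix <- function(x, ...) {
  cat(sprintf("<phyletic_matrix> %d families x %d genomes (%d presences)\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Look up the gene id carrying a family in a genome
#'
#' @param matrix A [phyletic_matrix()].
#' @param family_id,genome_id Identifiers.
#' @return Gene id, or `NA_character_` when unmapped.
#' @export
family_gene <- function(matrix, family_id, genome_id) {
  m <- matrix$family_to_gene
  if (is.null(m)) return(NA_character_)
  hit <- m$gene_id[m$family_id == family_id & m$genome_id == genome_id]
  if (length(hit)) hit[[1L]] else NA_character_
}

#' A named set of HGT candidate genes
#'
#' One candidate set per parsimony penalty ratio (or per external method under
#' benchmarking): for each genome, the genes inferred to have been gained on
#' that genome's terminal branch.
#'
#' @param name Set label, e.g. `"terminal.pen1"`.
#' @param candidates Named list: genome id -> character vector of gene ids.
#' @param penalty_ratio Gain/loss penalty ratio that produced the set (or `NA`
#'   for external sets).
#' @return An object of class `hgt_candidate_set`.
#' @export
hgt_candidate_set <- function(name, candidates, penalty_ratio = NA_real_) {
  if (is.null(names(candidates)) && length(candidates))
    abort_validation("candidates must be a named list (genome -> genes)")
  candidates <- lapply(candidates, function(g) sort(unique(as.character(g))))
  structure(list(name = as.character(name), candidates = candidates,
                 penalty_ratio = as.numeric(penalty_ratio)),
            class = "hgt_candidate_set")
}

#' @export
print.hgt_candidate_set <- function(x, ...) {
  cat(sprintf("<hgt_candidate_set> '%s': %d candidates in %d genomes (P_g/P_l = %s)\n",
              x$name, sum(lengths(x$candidates)), length(x$candidates),
              format(x$penalty_ratio)))
  invisible(x)
}

#' Total number of candidate genes in a set
#' @param set An [hgt_candidate_set()].
#' @return Integer count over all genomes.
#' @export
candidate_count <- function(set) sum(lengths(set$candidates))

#' Metabolic coupling network
#'
#' The gene universe of a metabolic reconstruction plus the pairs of genes
#' whose reactions are fully flux-coupled (any flux through one enforces a
#' proportional flux through the other).  Treated as an undirected simple
#' graph whose topology is fixed under randomization.
#'
#' @param nodes Character vector of gene ids (the node universe, size n).
#' @param pairs Two-column data.frame or matrix of coupled gene pairs
#'   (unordered; duplicates collapsed, size L1 after deduplication).
#' @return An object of class `coupling_network` with elements `nodes` and
#'   `pairs` (a data.frame with columns `gene_a`, `gene_b`, canonically
#'   ordered).
#' @export
coupling_network <- function(nodes, pairs) {
  nodes <- unique(as.character(nodes))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2 && nrow(pairs) > 0)
    abort_validation("pairs must have two gene columns")
  if (nrow(pairs)) {
    a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
    if (any(a == b))
      abort_validation(sprintf("self-pair not allowed: %s",
                               a[which(a == b)[1L]]))
    unknown <- setdiff(c(a, b), nodes)
    if (length(unknown))
      abort_validation(sprintf("pair gene not in node universe: %s",
                               unknown[[1L]]))
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi))
    pairs <- data.frame(gene_a = lo[keep], gene_b = hi[keep],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, pairs = pairs), class = "coupling_network")
}

#' @export
print.coupling_network <- function(x, ...) {
  cat(sprintf("<coupling_network> n = %d genes, L1 = %d coupled pairs\n",
              length(x$nodes), nrow(x$pairs)))
  invisible(x)
}

#' Result of one clustering analysis
#'
#' Bundles the observed pair count, its null expectation, the clustering
#' score CC = observed/expected and the one-sided permutation p-value
#' (r + 1)/(R + 1), where r is the number of randomizations whose statistic
#' is at least the observed value.
#'
#' @param observed Non-negative integer count of clustered pairs.
#' @param expected Null expectation of the count.
#' @param p_value Permutation p-value.
#' @param n_randomizations Number of randomizations R.
#' @param seed Seed used for the randomizations.
#' @param statistic `"spatial"` or `"metabolic"`.
#' @param set_name Candidate-set label.
#' @param n_candidates Number of candidate genes scored.
#' @return An object of class `clustering_result`.
#' @export
clustering_result <- function(observed, expected, p_value, n_randomizations,
                              seed, statistic = NA_character_,
                              set_name = NA_character_,
                              n_candidates = NA_integer_) {
  structure(
    list(set_name = set_name, statistic = statistic,
         n_candidates = as.integer(n_candidates),
         observed = observed, expected = expected,
         cc = clustering_score(observed, expected),
         p_value = p_value, n_randomizations = as.integer(n_randomizations),
         seed = as.integer(seed)),
    class = "clustering_result")
}

#' Clustering score CC = observed / expected
#'
#' CC >> 1 indicates clustering in excess of the null model; CC < 1 indicates
#' less clustering than expected.  When the expectation is zero the ratio is
#' undefined: `Inf` (with a warning) if pairs were nevertheless observed,
#' `NA` if none were.
#'
#' @param observed Observed pair count.
#' @param expected Expected pair count under the null.
#' @return The clustering score.
#' @export
clustering_score <- function(observed, expected) {
  if (is.na(expected) || is.na(observed)) return(NA_real_)
  if (expected > 0) return(observed / expected)
  if (observed > 0) {
    warning("expected count is 0 with observed > 0; clustering score is Inf")
    return(Inf)
  }
  NA_real_
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result> %s / %s: observed %s, expected %s, CC = %s, p = %s (R = %d)\n",
    x$set_name, x$statistic, format(x$observed),
    format(round(x$expected, 3)), format(round(x$cc, 3)),
    format(x$p_value), x$n_randomizations))
  invisible(x)
}

#' @export
as.data.frame.clustering_result <- function(x, ...) {
  data.frame(set_name = x$set_name, statistic = x$statistic,
             n_candidates = x$n_candidates, observed = x$observed,
             expected = x$expected, cc = x$cc, p_value = x$p_value,
             n_randomizations = x$n_randomizations, seed = x$seed,
             stringsAsFactors = FALSE)
}

# Deterministic substream seed derived from (seed, key string), so per-genome
# randomization streams do not depend on genome iteration order.  Plain
# polynomial string hash folded into [0, 2^31 - 2].
substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.double(seed) %% 2147483647 + h) %% 2147483647)
}
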