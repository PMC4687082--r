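# Readers/writers for the plain-text formats the pipeline touches:
# gene-order TSV / GFF3, presence-absence TSV, Newick, coupled-pair lists,
# candidate-set TSV, and the result report (TSV/JSON).

# Ragged-row check shared by the TSV readers; names the first offending line.
check_rectangular <- function(path, sep = "\t") {
  nf <- tryCatch(utils::count.fields(path, sep = sep, quote = "",
                                     comment.char = ""),
                 error = function(e) abort_parse(conditionMessage(e)))
  if (length(nf) == 0) return(invisible(0L))
  bad <- which(nf != nf[[1L]])
  if (length(bad))
    abort_parse(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                        path, bad[[1L]], nf[bad[[1L]]], nf[[1L]]))
  invisible(nf[[1L]])
}

#' Read per-replicon gene orders
#'
#' Reads ordered gene lists, one [genome_gene_order()] per replicon, from
#' either a gene-order TSV (columns `genome_id`, `replicon_id`, `gene_id`,
#' optional `position`, `is_examined` 0/1, `is_plasmid` 0/1) or a GFF3 file
#' of `gene` features (1-based start coordinates).  For GFF3 the gene order
#' is determined by sorting on start coordinate, ties broken by end
#' coordinate then gene id, so it is invariant to input line order; for TSV
#' the `position` column (if present) or the file order is used.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gff3"`.
#' @param exclude_plasmids Drop replicons flagged as plasmids.
#' @param genome_id Genome id for GFF3 input (no genome column there);
#'   defaults to the file name without extension.
#' @param plasmid_replicons Character vector of replicon ids to treat as
#'   plasmids (the only plasmid heuristic applied to GFF3 input).
#' @return List of [genome_gene_order()] objects, one per replicon.
#' @export
read_gene_order <- function(path, format = c("tsv", "gff3"),
                            exclude_plasmids = FALSE, genome_id = NULL,
                            plasmid_replicons = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  orders <- if (format == "tsv") {
    read_gene_order_tsv(path, plasmid_replicons)
  } else {
    read_gene_order_gff3(path, genome_id, plasmid_replicons)
  }
  if (exclude_plasmids)
    orders <- Filter(function(o) !o$is_plasmid, orders)
  orders
}

read_gene_order_tsv <- function(path, plasmid_replicons) {
  if (length(readLines(path, n = 1L)) == 0) return(list())
  check_rectangular(path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("genome_id", "replicon_id", "gene_id")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    abort_parse(sprintf("gene order TSV lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  if (!"is_examined" %in% names(d)) d$is_examined <- "1"
  if (!"is_plasmid" %in% names(d)) d$is_plasmid <- "0"
  if ("position" %in% names(d)) {
    pos <- suppressWarnings(as.numeric(d$position))
    if (anyNA(pos)) abort_parse("non-numeric position entry")
  } else pos <- seq_len(nrow(d))
  key <- paste(d$genome_id, d$replicon_id, sep = "\r")
  lapply(split(seq_len(nrow(d)), key)[unique(key)], function(i) {
    i <- i[order(pos[i])]
    genome_gene_order(
      genome_id = d$genome_id[i[[1L]]],
      replicon_id = d$replicon_id[i[[1L]]],
      genes = d$gene_id[i],
      is_examined = d$is_examined[i] != "0",
      is_plasmid = d$is_plasmid[i[[1L]]] != "0" ||
        d$replicon_id[i[[1L]]] %in% plasmid_replicons)
  }) |> unname()
}

read_gene_order_gff3 <- function(path, genome_id, plasmid_replicons) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (!length(grep("^[^#[:space:]]", lines))) return(list())
  g <- tryCatch(ape::read.gff(path, GFF3 = TRUE),
                error = function(e) abort_parse(sprintf(
                  "malformed GFF3 in %s: %s", path, conditionMessage(e))))
  g <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(g)) return(list())
  ids <- gff_attribute(g$attributes, "ID")
  lt <- gff_attribute(g$attributes, "locus_tag")
  ids[is.na(ids)] <- lt[is.na(ids)]
  if (anyNA(ids))
    abort_parse("GFF3 gene feature without ID or locus_tag attribute")
  lapply(split(seq_len(nrow(g)), as.character(g$seqid), drop = TRUE),
         function(i) {
           i <- i[order(g$start[i], g$end[i], ids[i])]
           genome_gene_order(
             genome_id = genome_id,
             replicon_id = as.character(g$seqid[i[[1L]]]),
             genes = ids[i],
             is_plasmid = as.character(g$seqid[i[[1L]]]) %in% plasmid_replicons)
         }) |> unname()
}

gff_attribute <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attributes))
  out <- rep(NA_character_, length(attributes))
  out[regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attributes) != -1L] <-
    sub(paste0("^(;)?\\s*", key, "="), "", m)
  out
}

#' Write gene orders to the gene-order TSV format
#'
#' @param orders List of [genome_gene_order()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(orders, path) {
  rows <- lapply(orders, function(o)
    data.frame(genome_id = o$genome_id, replicon_id = o$replicon_id,
               gene_id = o$genes, position = seq_along(o$genes) - 1L,
               is_examined = as.integer(o$is_examined),
               is_plasmid = as.integer(o$is_plasmid),
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-family presence/absence matrix
#'
#' TSV with a header row of genome ids; each body row is a family id followed
#' by 0/1 entries.  An optional sidecar TSV (columns `family_id`, `genome_id`,
#' `gene_id`) maps presences to concrete genes.
#'
#' @param path Matrix TSV.
#' @param family_to_gene_path Optional sidecar TSV.
#' @return A [phyletic_matrix()].
#' @export
read_phyletic_matrix <- function(path, family_to_gene_path = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  check_rectangular(path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2) abort_parse("matrix TSV needs a family column plus genomes")
  fam <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- unique(as.vector(m[is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m))))]))
    abort_validation(sprintf("non-numeric matrix entry: %s",
                             paste(utils::head(bad, 3), collapse = ", ")))
  }
  rownames(m) <- fam
  f2g <- NULL
  if (!is.null(family_to_gene_path)) {
    check_rectangular(family_to_gene_path)
    f2g <- utils::read.delim(family_to_gene_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  phyletic_matrix(m, f2g)
}

#' Write a presence/absence matrix (round-trip of [read_phyletic_matrix()])
#'
#' @param matrix A [phyletic_matrix()].
#' @param path Matrix TSV output.
#' @param family_to_gene_path Optional sidecar TSV output.
#' @return `path`, invisibly.
#' @export
write_phyletic_matrix <- function(matrix, path, family_to_gene_path = NULL) {
  d <- data.frame(family_id = rownames(matrix$presence),
                  matrix$presence, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(family_to_gene_path) && !is.null(matrix$family_to_gene))
    utils::write.table(matrix$family_to_gene, family_to_gene_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Tip labels are preserved verbatim and must be unique.  Rootedness is
#' checked where it matters (the parsimony step rejects unrooted trees);
#' multifurcating trees are allowed.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_parse(sprintf(
                     "malformed Newick in %s: %s", path, conditionMessage(e))))
  if (is.null(tree)) abort_parse(sprintf("malformed Newick in %s", path))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label))
    abort_validation(sprintf("duplicate tip label: %s",
                             tree$tip.label[duplicated(tree$tip.label)][[1L]]))
  tree
}

#' Read a metabolic coupling network
#'
#' @param pairs_path TSV with columns `gene_a`, `gene_b` (fully coupled gene
#'   pairs); deduplicated as unordered pairs.
#' @param universe_path Text file listing one gene id per line (the node
#'   universe the null model redistributes candidate status over).
#' @return A [coupling_network()].
#' @export
read_coupling_network <- function(pairs_path, universe_path) {
  for (p in c(pairs_path, universe_path))
    if (!file.exists(p)) abort_io(sprintf("file not found: %s", p))
  nodes <- trimws(readLines(universe_path))
  nodes <- nodes[nzchar(nodes)]
  if (length(readLines(pairs_path, n = 1L)) == 0) {
    pairs <- data.frame(gene_a = character(), gene_b = character())
  } else {
    check_rectangular(pairs_path)
    pairs <- utils::read.delim(pairs_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    if (!all(c("gene_a", "gene_b") %in% names(pairs)))
      abort_parse("pairs TSV needs columns gene_a and gene_b")
    pairs <- pairs[, c("gene_a", "gene_b")]
  }
  coupling_network(nodes, pairs)
}

#' Write a coupling network back to its two text files
#'
#' @param network A [coupling_network()].
#' @param pairs_path,universe_path Output paths.
#' @return `pairs_path`, invisibly.
#' @export
write_coupling_network <- function(network, pairs_path, universe_path) {
  utils::write.table(network$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(network$nodes, universe_path)
  invisible(pairs_path)
}

#' Read/write HGT candidate sets
#'
#' The candidate-set TSV has columns `set_name`, `genome_id`, `gene_id`,
#' `penalty_ratio`; one file can hold several sets.
#'
#' @param path Candidate-set TSV.
#' @return `read_candidate_sets()`: a named list of [hgt_candidate_set()].
#' @export
read_candidate_sets <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  check_rectangular(path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("set_name", "genome_id", "gene_id")
  if (!all(req %in% names(d)))
    abort_parse("candidate TSV needs columns set_name, genome_id, gene_id")
  if (!"penalty_ratio" %in% names(d)) d$penalty_ratio <- NA
  sets <- lapply(split(d, d$set_name), function(s)
    hgt_candidate_set(s$set_name[[1L]],
                      split(s$gene_id, s$genome_id),
                      suppressWarnings(as.numeric(s$penalty_ratio[[1L]]))))
  sets
}

#' @rdname read_candidate_sets
#' @param sets List of [hgt_candidate_set()] (or a single set).
#' @return `write_candidate_sets()`: `path`, invisibly.
#' @export
write_candidate_sets <- function(sets, path) {
  if (inherits(sets, "hgt_candidate_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    if (!sum(lengths(s$candidates)))
      return(NULL)
    data.frame(set_name = s$name,
               genome_id = rep(names(s$candidates), lengths(s$candidates)),
               gene_id = unlist(s$candidates, use.names = FALSE),
               penalty_ratio = s$penalty_ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), genome_id = character(),
                      gene_id = character(), penalty_ratio = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' One record per [clustering_result()], with all numeric fields serialized
#' at full precision.  The JSON form round-trips bit-identically.
#'
#' @param results List of [clustering_result()] (or a single result).
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "clustering_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(df))
    df <- as.data.frame(clustering_result(0L, 0, 1, 1L, 0L))[0L, ]
  ok <- tryCatch({
    if (format == "tsv") {
      chr <- df
      for (j in seq_along(chr))
        if (is.double(chr[[j]])) chr[[j]] <- sprintf("%.17g", chr[[j]])
      utils::write.table(chr, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", digits = I(17),
                           na = "null", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(sprintf("cannot write report to %s: %s", path,
                                    conditionMessage(ok)))
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report file.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame of result records.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
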