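test_that("gene order TSV reader echoes input order and attributes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tgene_id",
               "G1\tchr\tg1", "G1\tchr\tg2", "G1\tchr\tg3"), f)
  orders <- read_gene_order(f, "tsv")
  expect_length(orders, 1L)
  expect_identical(orders[[1L]]$genes, c("g1", "g2", "g3"))
  expect_true(all(orders[[1L]]$is_examined))
  expect_false(orders[[1L]]$is_plasmid)
})

test_that("gene order TSV honours position, flags, and plasmid exclusion", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\treplicon_id\tgene_id\tposition\tis_examined\tis_plasmid",
    "G1\tchr\tgB\t2\t1\t0",
    "G1\tchr\tgA\t1\t0\t0",
    "G1\tpls\tgP\t1\t1\t1"), f)
  orders <- read_gene_order(f, "tsv")
  expect_length(orders, 2L)
  chr <- orders[[which(vapply(orders, function(o) o$replicon_id, "") == "chr")]]
  expect_identical(chr$genes, c("gA", "gB"))
  expect_identical(chr$is_examined, c(FALSE, TRUE))
  no_pls <- read_gene_order(f, "tsv", exclude_plasmids = TRUE)
  expect_length(no_pls, 1L)
  expect_identical(no_pls[[1L]]$replicon_id, "chr")
})

test_that("gene order reader rejects duplicates and empty input is empty", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tgene_id",
               "G1\tchr\tg1", "G1\tchr\tg1"), f)
  expect_error(read_gene_order(f, "tsv"), class = "hgt_validation_error")
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_identical(read_gene_order(empty, "tsv"), list())
})

gff_line <- function(seqid, start, end, id)
  sprintf("%s\t.\tgene\t%d\t%d\t.\t+\t.\tID=%s", seqid, start, end, id)

test_that("GFF3 genes are ordered by start coordinate, not line order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               gff_line("chr", 500, 900, "late"),
               gff_line("chr", 100, 400, "early")), f)
  orders <- read_gene_order(f, "gff3", genome_id = "G1")
  expect_identical(orders[[1L]]$genes, c("early", "late"))
  # invariance to input line order
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               gff_line("chr", 100, 400, "early"),
               gff_line("chr", 500, 900, "late")), f2)
  orders2 <- read_gene_order(f2, "gff3", genome_id = "G1")
  expect_identical(orders[[1L]]$genes, orders2[[1L]]$genes)
})

test_that("phyletic matrix reader validates binary entries and shape", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tA\tB\tC", "f1\t1\t1\t1", "f2\t1\t1\t1"), f)
  m <- read_phyletic_matrix(f)
  expect_identical(dim(m$presence), c(2L, 3L))
  expect_identical(sum(m$presence), 6L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tA\tB", "f1\t2\t1"), bad)
  expect_error(read_phyletic_matrix(bad), class = "hgt_validation_error")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tA\tB", "f1\t1"), ragged)
  expect_error(read_phyletic_matrix(ragged), class = "hgt_parse_error")
})

test_that("phyletic matrix round-trips exactly through write/read", {
  pres <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), nrow = 2,
                 dimnames = list(c("f1", "f2"), c("A", "B", "C")))
  f2g <- data.frame(family_id = c("f1", "f1", "f2"),
                    genome_id = c("A", "C", "A"),
                    gene_id = c("a1", "c1", "a2"), stringsAsFactors = FALSE)
  m <- phyletic_matrix(pres, f2g)
  fm <- withr::local_tempfile(fileext = ".tsv")
  fg <- withr::local_tempfile(fileext = ".tsv")
  write_phyletic_matrix(m, fm, fg)
  back <- read_phyletic_matrix(fm, fg)
  expect_identical(back$presence, m$presence)
  expect_identical(back$family_to_gene, m$family_to_gene)
  expect_identical(family_gene(back, "f1", "C"), "c1")
  expect_identical(family_gene(back, "f2", "C"), NA_character_)
})

test_that("phyletic matrix constructor rejects inconsistent gene maps", {
  pres <- matrix(c(1L, 0L), nrow = 1, dimnames = list("f1", c("A", "B")))
  expect_error(
    phyletic_matrix(pres, data.frame(family_id = "f1", genome_id = "B",
                                     gene_id = "b1")),
    class = "hgt_validation_error")
})

test_that("Newick reader handles bifurcating, multifurcating, bad input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", f)
  tr <- read_tree(f)
  expect_length(tr$tip.label, 4L)
  expect_identical(tr$Nnode, 3L)

  writeLines("(A,B,C);", f)
  tri <- read_tree(f)
  expect_length(tri$tip.label, 3L)
  expect_identical(tri$Nnode, 1L)

  writeLines("((A,A),B);", f)
  expect_error(read_tree(f), class = "hgt_validation_error")
  writeLines("((A,B),(C,D);", f)
  expect_error(read_tree(f), class = "hgt_parse_error")
})

test_that("coupling network reader deduplicates unordered pairs", {
  fp <- withr::local_tempfile(fileext = ".tsv")
  fu <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("gene_a\tgene_b", "a\tb", "b\ta"), fp)
  writeLines(c("a", "b", "c"), fu)
  net <- read_coupling_network(fp, fu)
  expect_identical(nrow(net$pairs), 1L)
  expect_length(net$nodes, 3L)

  writeLines(c("gene_a\tgene_b", "a\ta"), fp)
  expect_error(read_coupling_network(fp, fu), class = "hgt_validation_error")
  writeLines(c("gene_a\tgene_b", "a\tz"), fp)
  expect_error(read_coupling_network(fp, fu), "z")

  file.create(fp2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_identical(nrow(read_coupling_network(fp2, fu)$pairs), 0L)
})

test_that("coupling network read is idempotent over its own output", {
  net <- coupling_network(c("a", "b", "c", "d"),
                          data.frame(gene_a = c("c", "a"),
                                     gene_b = c("a", "b")))
  fp <- withr::local_tempfile(fileext = ".tsv")
  fu <- withr::local_tempfile(fileext = ".txt")
  write_coupling_network(net, fp, fu)
  back <- read_coupling_network(fp, fu)
  expect_identical(nrow(back$pairs), nrow(net$pairs))
  expect_identical(sort(back$nodes), sort(net$nodes))
})

test_that("report writer emits the score fields and round-trips JSON exactly", {
  res <- clustering_result(observed = 882L, expected = 540.178,
                           p_value = 0.001, n_randomizations = 999L,
                           seed = 7L, statistic = "spatial",
                           set_name = "terminal.pen1", n_candidates = 2020L)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, ft, "tsv")
  tab <- read_report(ft, "tsv")
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$observed, 882L)
  expect_equal(tab$expected, 540.178)
  expect_equal(tab$cc, 882 / 540.178)

  fj <- withr::local_tempfile(fileext = ".json")
  write_report(res, fj, "json")
  back <- read_report(fj, "json")
  for (fld in c("observed", "expected", "cc", "p_value"))
    expect_identical(back[[fld]], as.data.frame(res)[[fld]])

  write_report(list(), ft, "tsv")
  expect_identical(nrow(read_report(ft, "tsv")), 0L)
  expect_true(grepl("observed", readLines(ft)[[1L]]))
})

test_that("candidate-set TSV round-trips sets and penalty ratios", {
  sets <- list(hgt_candidate_set("pen1", list(A = c("a1", "a2"),
                                              B = "b1"), 1),
               hgt_candidate_set("pen2", list(A = "a1", B = character()), 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_sets(sets, f)
  back <- read_candidate_sets(f)
  expect_identical(back$pen1$candidates$A, c("a1", "a2"))
  expect_identical(candidate_count(back$pen2), 1L)
  expect_identical(back$pen2$penalty_ratio, 2)
})
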