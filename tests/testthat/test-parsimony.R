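test_that("minimal costs match hand-checked four-tip cases", {
  tr <- quad_tree()
  expect_equal(sankoff_min_cost(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  expect_equal(sankoff_min_cost(tr, c(A = 0, B = 0, C = 0, D = 0)), 0)
  # single-tip presence: one gain at ratio 1; ties gain/loss scenarios at 2
  p <- c(A = 1, B = 0, C = 0, D = 0)
  expect_equal(sankoff_min_cost(tr, p), 1)
  expect_equal(sankoff_min_cost(tr, p, parsimony_config(2, 1)), 2)
  # brute-force confirmation
  expect_equal(sankoff_min_cost(tr, p), brute_force_sankoff(tr, p, 1, 1))
  expect_equal(sankoff_min_cost(tr, p, parsimony_config(2, 1)),
               brute_force_sankoff(tr, p, 2, 1))
})

test_that("costs equal brute force on random trees, patterns, penalties", {
  set.seed(42)
  for (rep in 1:30) {
    ntip <- sample(3:6, 1L)
    tr <- ape::rtree(ntip, tip.label = LETTERS[seq_len(ntip)])
    pattern <- stats::setNames(sample(0:1, ntip, replace = TRUE),
                               tr$tip.label)
    pg <- sample(c(1, 2), 1L)
    expect_equal(sankoff_min_cost(tr, pattern, parsimony_config(pg, 1)),
                 brute_force_sankoff(tr, pattern, pg, 1))
  }
})

test_that("DELTRAN places the unique minimum reconstructions correctly", {
  tr <- quad_tree()
  rec <- reconstruct_deltran(tr, c(A = 1, B = 0, C = 0, D = 0))
  ev <- rec$events[rec$events$event != "none", ]
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$label, "A")
  expect_identical(ev$event, "gain")
  expect_true(ev$is_terminal)

  rec2 <- reconstruct_deltran(tr, c(A = 1, B = 1, C = 0, D = 0))
  ev2 <- rec2$events[rec2$events$event != "none", ]
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$event, "gain")
  expect_false(ev2$is_terminal)

  rec3 <- reconstruct_deltran(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_identical(sum(rec3$events$event != "none"), 0L)
  expect_equal(rec3$total_cost, 0)
})

test_that("DELTRAN breaks the ratio-2 gain/loss tie toward the terminal gain", {
  # convention-dependent case: gain-on-A (cost 2) ties a loss-based scenario
  tr <- quad_tree()
  rec <- reconstruct_deltran(tr, c(A = 1, B = 0, C = 0, D = 0),
                             parsimony_config(2, 1))
  ev <- rec$events[rec$events$event != "none", ]
  expect_identical(ev$label, "A")
  expect_identical(ev$event, "gain")
  expect_equal(rec$total_cost, 2)
})

test_that("DELTRAN event costs always sum to the Sankoff minimum", {
  set.seed(7)
  for (rep in 1:40) {
    ntip <- sample(3:7, 1L)
    tr <- ape::rtree(ntip)
    pattern <- stats::setNames(sample(0:1, ntip, replace = TRUE),
                               tr$tip.label)
    cfg <- parsimony_config(sample(c(1, 2), 1L), 1)
    rec <- reconstruct_deltran(tr, pattern, cfg)
    expect_equal(rec$total_cost, sankoff_min_cost(tr, pattern, cfg))
    # states consistent with events and tips
    expect_identical(rec$ancestral_states[seq_len(ntip)],
                     as.integer(pattern[tr$tip.label]))
  }
})

test_that("multifurcations are handled, unrooted trees are rejected", {
  # internal polytomy under a binary root is fine; a basal polytomy is the
  # Newick convention for an unrooted tree and is rejected
  tri <- ape::read.tree(text = "((A,B,C),D);")
  expect_equal(sankoff_min_cost(tri, c(A = 1, B = 0, C = 0, D = 0)), 1)
  expect_error(sankoff_min_cost(ape::read.tree(text = "(A,B,C,D);"),
                                c(A = 1, B = 0, C = 0, D = 0)),
               class = "hgt_validation_error")
  unr <- ape::unroot(ape::rtree(5))
  pat <- stats::setNames(rep(1, 5), unr$tip.label)
  expect_error(sankoff_min_cost(unr, pat), class = "hgt_validation_error")
  expect_error(sankoff_min_cost(quad_tree(), c(A = 1, B = 0, C = 0)),
               class = "hgt_validation_error")
})

test_that("tip relabelling by a tree automorphism permutes events identically", {
  tr <- quad_tree()
  # swapping A and B is an automorphism of ((A,B),(C,D))
  rec_a <- reconstruct_deltran(tr, c(A = 1, B = 0, C = 0, D = 0))
  rec_b <- reconstruct_deltran(tr, c(A = 0, B = 1, C = 0, D = 0))
  lab_a <- rec_a$events$label[rec_a$events$event == "gain"]
  lab_b <- rec_b$events$label[rec_b$events$event == "gain"]
  expect_identical(lab_a, "A")
  expect_identical(lab_b, "B")
  expect_equal(rec_a$total_cost, rec_b$total_cost)
})

test_that("gain totals do not increase when the gain penalty rises", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- ape::rtree(6)
    sim <- simulate_family_evolution(tr, n_root_families = 40L,
                                     loss_rate = 0.15,
                                     terminal_gain_count = 3L, seed = rep)
    gains <- vapply(c(1, 2), function(pg) {
      tot <- 0L
      for (fam in rownames(sim$matrix$presence)) {
        rec <- reconstruct_deltran(tr, sim$matrix$presence[fam, ],
                                   parsimony_config(pg, 1))
        tot <- tot + sum(rec$events$event == "gain")
      }
      tot
    }, 0L)
    expect_gte(gains[[1L]], gains[[2L]])
  }
})

make_single_tip_matrix <- function(examined = TRUE) {
  pres <- matrix(c(1L, 0L, 0L, 0L), nrow = 1,
                 dimnames = list("f1", c("A", "B", "C", "D")))
  m <- phyletic_matrix(pres, data.frame(family_id = "f1", genome_id = "A",
                                        gene_id = "gA"))
  orders <- list(genome_gene_order("A", "chr", c("gA", "gX"),
                                   is_examined = c(examined, TRUE)),
                 genome_gene_order("B", "chr", "gB"),
                 genome_gene_order("C", "chr", "gC"),
                 genome_gene_order("D", "chr", "gD"))
  list(matrix = m, orders = orders)
}

test_that("terminal gains become candidates; singletons and plasmids never do", {
  tr <- quad_tree()
  w <- make_single_tip_matrix()
  set <- terminal_hgt_candidates(w$matrix, tr, orders = w$orders)
  expect_identical(set$candidates$A, "gA")
  expect_identical(candidate_count(set), 1L)
  expect_identical(set$name, "terminal.pen1")

  # same family flagged as a singleton (unexamined gene): never a candidate
  ws <- make_single_tip_matrix(examined = FALSE)
  set_s <- terminal_hgt_candidates(ws$matrix, tr, orders = ws$orders)
  expect_identical(candidate_count(set_s), 0L)

  # plasmid-borne gene: excluded
  wp <- make_single_tip_matrix()
  wp$orders[[1L]] <- genome_gene_order("A", "pls", c("gA", "gX"),
                                       is_plasmid = TRUE)
  set_p <- terminal_hgt_candidates(wp$matrix, tr, orders = wp$orders)
  expect_identical(candidate_count(set_p), 0L)

  # family present everywhere contributes nothing
  pres <- matrix(1L, nrow = 1, ncol = 4,
                 dimnames = list("f1", c("A", "B", "C", "D")))
  all1 <- phyletic_matrix(pres, data.frame(
    family_id = "f1", genome_id = c("A", "B", "C", "D"),
    gene_id = c("gA", "gB", "gC", "gD")))
  expect_identical(candidate_count(terminal_hgt_candidates(all1, tr)), 0L)
})

test_that("missing gene mapping for a terminal gain is an error", {
  tr <- quad_tree()
  pres <- matrix(c(1L, 0L, 0L, 0L), nrow = 1,
                 dimnames = list("f1", c("A", "B", "C", "D")))
  m <- phyletic_matrix(pres)  # no family_to_gene at all
  expect_error(terminal_hgt_candidates(m, tr),
               class = "hgt_validation_error")
})

test_that("candidate-set comparison reports overlap and differences", {
  a <- hgt_candidate_set("a", list(G = c("g1", "g2", "g3")), 1)
  b <- hgt_candidate_set("b", list(G = "g2"), 2)
  cmp <- compare_candidate_sets(a, b)
  expect_identical(cmp$total[["intersection"]], 1L)
  expect_identical(cmp$total[["a_only"]], 2L)
  expect_identical(cmp$total[["union"]], 3L)

  same <- compare_candidate_sets(a, a)
  expect_identical(same$total[["intersection"]], 3L)
  expect_identical(same$total[["a_only"]], 0L)

  d1 <- hgt_candidate_set("d1", list(G = c("x1", "x2", "x3")), 1)
  d2 <- hgt_candidate_set("d2", list(G = c("y1", "y2")), 1)
  cmp2 <- compare_candidate_sets(d1, d2)
  expect_identical(cmp2$total[["intersection"]], 0L)
  expect_identical(cmp2$total[["union"]], 5L)

  expect_error(compare_candidate_sets(a, hgt_candidate_set("c", list(H = "h1"))),
               class = "hgt_validation_error")
})
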