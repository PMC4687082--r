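# Independent oracles used to freeze expected values: brute-force parsimony
# by exhaustive enumeration of ancestral assignments, and the neighbour-pair
# expectation by exhaustive enumeration of candidate placements.  These
# deliberately share no code with the package implementations.

# Minimal gain/loss cost by trying every assignment of 0/1 to internal nodes.
brute_force_sankoff <- function(tree, pattern, pg = 1, pl = 1) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  tip_states <- as.integer(pattern[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    st <- c(tip_states, as.integer(intToBits(mask))[seq_len(m)])
    cost <- 0
    for (k in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[k, 1L]]
      b <- st[tree$edge[k, 2L]]
      cost <- cost + (if (a == 0 && b == 1) pg else if (a == 1 && b == 0) pl
                      else 0)
    }
    best <- min(best, cost)
  }
  best
}

# Vectorized variant: minimal cost for ALL 2^ntip tip patterns at once
# (pattern q has tip j in state bit_j(q)).  Same enumeration, reshaped.
brute_force_sankoff_all_patterns <- function(tree, pg = 1, pl = 1) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  A <- sapply(seq_len(m), function(j)
    bitwAnd(bitwShiftR(0:(2^m - 1), j - 1L), 1L))
  A <- matrix(A, ncol = m)
  P <- sapply(seq_len(ntip), function(j)
    bitwAnd(bitwShiftR(0:(2^ntip - 1), j - 1L), 1L))
  P <- matrix(P, ncol = ntip)
  M <- matrix(0, nrow = 2^m, ncol = 2^ntip)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    pa <- A[, p - ntip]
    if (ch <= ntip) {
      cb <- P[, ch]
      M <- M + pg * outer(pa == 0, cb == 1) + pl * outer(pa == 1, cb == 0)
    } else {
      cb <- A[, ch - ntip]
      M <- M + (pg * (pa == 0 & cb == 1) + pl * (pa == 1 & cb == 0))
    }
  }
  apply(M, 2L, min)
}

# Naive window-rule count: gene i qualifies iff flagged and any of the next
# w positions is flagged (explicit scan, no positional shortcuts).
naive_count_pairs <- function(flags, w, circular = FALSE) {
  n <- length(flags)
  total <- 0L
  for (i in seq_len(n)) {
    if (flags[i] != 1) next
    hit <- FALSE
    for (d in seq_len(w)) {
      j <- i + d
      if (circular) {
        if (d > n - 1) break
        j <- ((j - 1L) %% n) + 1L
      } else if (j > n) break
      if (flags[j] == 1) { hit <- TRUE; break }
    }
    total <- total + hit
  }
  total
}

# Exhaustive mean of the count over all C(n, c) uniform placements.
enum_expected_pairs <- function(n, c, w, circular = FALSE) {
  if (c == 0 || n == 0) return(0)
  placements <- utils::combn(n, c)
  tot <- 0
  for (j in seq_len(ncol(placements))) {
    flags <- integer(n)
    flags[placements[, j]] <- 1L
    tot <- tot + naive_count_pairs(flags, w, circular)
  }
  tot / ncol(placements)
}

# Exhaustive mean of coupled-pair counts over all C(n, n2) candidate subsets.
enum_expected_coupled <- function(network, n2) {
  nodes <- network$nodes
  subsets <- utils::combn(length(nodes), n2)
  tot <- 0
  for (j in seq_len(ncol(subsets))) {
    s <- nodes[subsets[, j]]
    tot <- tot + sum(network$pairs$gene_a %in% s & network$pairs$gene_b %in% s)
  }
  tot / ncol(subsets)
}

quad_tree <- function() ape::read.tree(text = "((A,B),(C,D));")

# small complete input set shared by io/pipeline tests
tiny_world <- function(seed = 11L) {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  simulate_family_evolution(tree, n_root_families = 30L, loss_rate = 0.05,
                            terminal_gain_count = 4L, gain_block_length = 2L,
                            seed = seed)
}
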