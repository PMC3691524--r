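# Independent oracles and fixture generators shared across the suite.
# Oracles deliberately avoid the package's Fitch/DP code paths: parsimony
# minima come from exhaustive enumeration over internal labelings, and
# folding optima from exhaustive enumeration over structures.

# every unlabeled rooted binary tree shape with 2..6 leaves
tree_shapes_newick <- c(
  "(a,b);",
  "((a,b),c);",
  "(((a,b),c),d);", "((a,b),(c,d));",
  "((((a,b),c),d),e);", "(((a,b),(c,d)),e);", "(((a,b),c),(d,e));",
  "(((((a,b),c),d),e),f);", "((((a,b),(c,d)),e),f);",
  "((((a,b),c),(d,e)),f);", "((a,b),(((c,d),e),f));",
  "((a,b),((c,d),(e,f)));", "(((a,b),c),((d,e),f));")

# exhaustive small-parsimony minimum: try internal labelings drawn from
# `alphabet` (integer codes), count edge mismatches, take the minimum.
# Returns a single integer.  `leaf_labels` in tip order (integer codes).
oracle_parsimony_min <- function(tree, leaf_labels, alphabet) {
  topo <- phylocofold:::tree_topology(tree)
  m <- topo$nnode
  r <- length(alphabet)
  if (m == 0L) return(0L)
  n_comb <- r^m
  stopifnot(n_comb <= 2e6)
  internal_ids <- sort(topo$internal)
  # edges as (parent, child) over ape node ids
  edges <- tree$edge
  int_pos <- function(id) match(id, internal_ids)
  best <- Inf
  for (comb in 0:(n_comb - 1L)) {
    lab <- integer(topo$ntip + m)
    lab[seq_len(topo$ntip)] <- leaf_labels
    rest <- comb
    for (z in seq_len(m)) {
      lab[internal_ids[z]] <- alphabet[rest %% r + 1L]
      rest <- rest %/% r
    }
    mis <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    if (mis < best) best <- mis
  }
  as.integer(best)
}

# vectorized variant: minimum over internal labelings for MANY leaf
# labelings at once.  leaf_lab_mat: ntip x n_labelings integer codes.
# Returns integer vector of length n_labelings.
oracle_parsimony_min_vec <- function(tree, leaf_lab_mat, alphabet) {
  topo <- phylocofold:::tree_topology(tree)
  m <- topo$nnode
  r <- length(alphabet)
  nl <- ncol(leaf_lab_mat)
  internal_ids <- sort(topo$internal)
  edges <- tree$edge
  int_edges <- edges[edges[, 2] > topo$ntip, , drop = FALSE]
  leaf_edges <- edges[edges[, 2] <= topo$ntip, , drop = FALSE]
  best <- rep(Inf, nl)
  for (comb in 0:(r^m - 1L)) {
    il <- integer(topo$ntip + m)
    rest <- comb
    for (z in seq_len(m)) {
      il[internal_ids[z]] <- alphabet[rest %% r + 1L]
      rest <- rest %/% r
    }
    const <- sum(il[int_edges[, 1]] != il[int_edges[, 2]])
    cost <- rep(const, nl)
    for (e in seq_len(nrow(leaf_edges))) {
      tip <- leaf_edges[e, 2]
      cost <- cost + (leaf_lab_mat[tip, ] != il[leaf_edges[e, 1]])
    }
    best <- pmin(best, cost)
  }
  as.integer(best)
}

# uniform random gapped alignment (not structure-aware)
rand_aln <- function(N, L, seed, gap_prob = 0.1) {
  set.seed(seed)
  chars <- c("A", "C", "G", "U")
  m <- matrix(sample(chars, N * L, replace = TRUE), N, L)
  if (gap_prob > 0)
    m[matrix(runif(N * L) < gap_prob, N, L)] <- "-"
  rna_alignment(apply(m, 1L, paste, collapse = ""),
                names = paste0("s", seq_len(N)))
}

# random non-crossing structure with n_pairs pairs on L columns
rand_struct <- function(L, n_pairs, seed) {
  set.seed(seed)
  pairs <- matrix(integer(0), 0, 2)
  for (tries in seq_len(50L)) {
    if (nrow(pairs) >= n_pairs) break
    i <- sample.int(L - 4L, 1L)
    j <- i + 3L + sample.int(L - i - 3L, 1L)
    cand <- rbind(pairs, c(i, j))
    ok <- !anyDuplicated(c(cand)) &&
      !phylocofold:::pairs_cross(cand[order(cand[, 1]), , drop = FALSE])
    if (ok) pairs <- cand
  }
  rna_structure(L, pairs)
}

# structured random instance: alignment evolved on a random tree with a
# known consensus structure (exercises folding with realistic masks)
rand_struct_instance <- function(seed, n_taxa = 4L, L = 12L,
                                 n_pairs = 2L, sub_rate = 0.2,
                                 switch_rate = 0.5, gap_prob = 0.05) {
  st <- rand_struct(L, n_pairs, seed * 7L + 1L)
  cfg <- sim_config(n_taxa, st, sub_rate = sub_rate,
                    switch_rate = switch_rate, gap_prob = gap_prob,
                    seed = seed)
  simulate_alignment(cfg)
}

balanced4_tree <- function() read_newick("((t1,t2),(t3,t4));")
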