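test_that("forward Fitch pass reproduces hand-worked cases", {
  tr <- read_newick("((x,y),(z,w));")
  r <- fitch_forward(tr, c(x = "A", y = "A", z = "G", w = "G"))
  expect_equal(r$cost, 1L)
  expect_setequal(r$labels, c("A", "G"))

  expect_equal(fitch_forward(tr, c(x = "C", y = "C", z = "C",
                                   w = "C"))$cost, 0L)
  expect_error(fitch_forward(tr, c(x = "A", y = "A", z = "G")),
               "unlabeled")
})

test_that("forward Fitch cost equals the exhaustive parsimony minimum", {
  # caterpillar example plus seeded random instances on small trees
  cat4 <- read_newick("(((x,y),z),w);")
  labs <- c(x = "A", y = "G", z = "A", w = "G")
  got <- fitch_forward(cat4, labs)$cost
  codes <- match(labs[cat4$tip.label], c("A", "C", "G", "U"))
  expect_equal(got, oracle_parsimony_min(cat4, codes, 1:4))

  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:6, 1L)
    tr <- ape::rtree(n)
    codes <- sample.int(4L, n, replace = TRUE)
    labs <- stats::setNames(c("A", "C", "G", "U")[codes], tr$tip.label)
    expect_equal(fitch_forward(tr, labs)$cost,
                 oracle_parsimony_min(tr, codes, 1:4),
                 info = paste("seed", seed))
  }
})

test_that("pair-label Fitch handles canonical and gap-sentinel leaves", {
  tr <- balanced4_tree()
  aln <- rna_alignment(c(t1 = "G..C", t2 = "G..C", t3 = "G..C",
                         t4 = "G..C"))
  expect_equal(pair_fitch(tr, aln, 1, 4), list(m = 0L, b = 4L))

  aln2 <- rna_alignment(c(t1 = "G..C", t2 = "G..C", t3 = "A..U",
                          t4 = "A..U"))
  expect_equal(pair_fitch(tr, aln2, 1, 4), list(m = 1L, b = 4L))

  # non-pairing row is transparent: GC vs AU across it still costs 1
  tr3 <- read_newick("((r1,r2),r3);")
  aln3 <- rna_alignment(c(r1 = "G..C", r2 = "A..G", r3 = "A..U"))
  expect_equal(pair_fitch(tr3, aln3, 1, 4), list(m = 1L, b = 2L))

  # all leaves non-pairing -> (0, 0)
  aln4 <- rna_alignment(c(t1 = "A..G", t2 = "C..C", t3 = "-..U",
                          t4 = "U..U"))
  expect_equal(pair_fitch(tr, aln4, 1, 4), list(m = 0L, b = 0L))

  expect_error(pair_fitch(tr, aln, 4, 1), "i < j")
  expect_error(pair_fitch(tr, aln, 1, 9), "out of range")
})

test_that("pair Fitch equals generic Fitch when no leaf is a sentinel", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(3:7, 1L)
    tr <- ape::rtree(n)
    prs <- sample(phylocofold:::CANONICAL_PAIRS, n, replace = TRUE)
    rows <- paste0(substr(prs, 1, 1), "---", substr(prs, 2, 2))
    aln <- rna_alignment(rows, names = tr$tip.label)
    got <- pair_fitch(tr, aln, 1, 5)
    expect_equal(got$b, n)
    expect_equal(got$m,
                 fitch_forward(tr, stats::setNames(prs, tr$tip.label))$cost)
  }
})

test_that("pair Fitch is invariant under consistent row permutation", {
  for (seed in 1:10) {
    sim <- rand_struct_instance(seed, n_taxa = 6L, L = 10L, n_pairs = 2L)
    aln <- sim$aln; tr <- sim$tree
    perm <- sample(nrow(aln$mat))
    aln2 <- rna_alignment(aln$seqs[perm], names = aln$names[perm])
    i <- sim$structure$pairs[1, 1]; j <- sim$structure$pairs[1, 2]
    expect_equal(pair_fitch(tr, aln, i, j), pair_fitch(tr, aln2, i, j))
  }
})

test_that("mutation count is bounded by the pair count", {
  for (seed in 1:20) {
    aln <- rand_aln(N = 6, L = 8, seed = seed, gap_prob = 0.2)
    set.seed(seed + 1000L)
    tr <- ape::rtree(6)
    tr$tip.label <- aln$names
    for (j in 2:8) {
      r <- pair_fitch(tr, aln, 1, j)
      expect_gte(r$m, 0L)
      expect_lte(r$m, max(r$b - 1L, 0L))
    }
  }
})

test_that("Jukes-Cantor distances follow the closed form and saturate", {
  a <- paste(rep("ACGU", 25), collapse = "")
  aln <- rna_alignment(c(x = a, y = a))
  expect_equal(unclass(distance_matrix(aln))["x", "y"], 0)

  # one difference in 100 positions
  b <- a
  substr(b, 1, 1) <- "G"
  d <- distance_matrix(rna_alignment(c(x = a, y = b)))
  p <- 1 / 100
  expect_equal(unclass(d)["x", "y"], -0.75 * log(1 - 4 * p / 3))

  # saturated pair (> 75% different) -> 1000
  x <- paste(rep("A", 20), collapse = "")
  y <- paste(rep("G", 20), collapse = "")
  expect_equal(unclass(distance_matrix(rna_alignment(c(x = x, y = y))))["x", "y"],
               1000)

  # agreement with ape's JC69 on a gapless fixture
  set.seed(7)
  m <- matrix(sample(c("a", "c", "g", "t"), 4 * 60, replace = TRUE), 4, 60)
  rownames(m) <- paste0("s", 1:4)
  dna <- ape::as.DNAbin(m)
  ours <- distance_matrix(rna_alignment(apply(toupper(m), 1, paste,
                                              collapse = "")))
  theirs <- as.matrix(ape::dist.dna(dna, model = "JC69"))
  ours <- unclass(ours)[rownames(theirs), colnames(theirs)]
  ok <- is.finite(theirs)  # ape returns NaN where we saturate to 1000
  expect_equal(ours[ok], theirs[ok], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(ours[!ok] == 1000))
})

test_that("UPGMA recovers topology and cophenetic distances", {
  dm <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  class(dm) <- c("dist_matrix", "matrix")
  tr <- upgma_tree(dm)
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))
  expect_true(ape::is.monophyletic(tr, c("a", "b")))

  # ultrametric matrix round-trips through cophenetic distances
  set.seed(11)
  base <- ape::rcoal(6)
  cd <- ape::cophenetic.phylo(base)
  class(cd) <- c("dist_matrix", "matrix")
  back <- upgma_tree(cd)
  expect_equal(ape::cophenetic.phylo(back)[rownames(cd), colnames(cd)],
               cd[rownames(cd), colnames(cd)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(upgma_tree(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
})
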