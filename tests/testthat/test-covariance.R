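make_cols_aln <- function(pairs_at_15) {
  # rows with the given 2-mers at columns 1 and 5, AAA in between
  rna_alignment(paste0(substr(pairs_at_15, 1, 1), "AAA",
                       substr(pairs_at_15, 2, 2)),
                names = paste0("s", seq_along(pairs_at_15)))
}

test_that("conservation score follows the pairwise Hamming rule", {
  p <- scoring_params(beta = 0)
  expect_equal(conservation_score(make_cols_aln(c("GC", "GC")), 1, 5, p), 0)
  expect_equal(conservation_score(make_cols_aln(c("GC", "AU")), 1, 5, p), 1)
  # non-pair rows contribute nothing
  expect_equal(conservation_score(make_cols_aln(c("GC", "GC", "AG")),
                                  1, 5, p), 0)
  # one mutation (GC vs GU): h = 0 + 1, one pair, N = 2
  expect_equal(conservation_score(make_cols_aln(c("GC", "GU")), 1, 5, p),
               0.5)
})

test_that("RIBOSUM mode scores with matrix entries", {
  p <- scoring_params(beta = 0, use_ribosum = TRUE)
  R <- p$ribosum
  expect_equal(p$phi1, 0.6)
  expect_equal(p$phi2, 0.5)
  aln <- make_cols_aln(c("GC", "AU"))
  expect_equal(conservation_score(aln, 1, 5, p), R["GC", "AU"] / 2)
  aln3 <- make_cols_aln(c("GC", "AU", "UA"))
  expect_equal(conservation_score(aln3, 1, 5, p),
               (R["GC", "AU"] + R["GC", "UA"] + R["AU", "UA"]) / 3)
})

test_that("penalty score charges non-pairing rows", {
  expect_equal(penalty_score(make_cols_aln(c("GC", "AU", "UG")), 1, 5), 0)
  aln <- rna_alignment(c(s1 = "GAAAC", s2 = "-AAA-", s3 = "AAAAG"))
  expect_equal(penalty_score(aln, 1, 5), 0 + 0.25 + 1)
  aln2 <- rna_alignment(c(s1 = "-AAAC", s2 = "GAAAC"))
  expect_equal(penalty_score(aln2, 1, 5), 1 + 0)
  # ambiguity codes never pair
  aln3 <- rna_alignment(c(s1 = "NAAAC", s2 = "GAAAC"))
  expect_equal(penalty_score(aln3, 1, 5), 1 + 0)
})

test_that("gamma combines conservation and penalty", {
  expect_equal(baseline_gamma(1, 0, scoring_params()), 1)
  expect_equal(baseline_gamma(0, 2, scoring_params(phi1 = 0.6)), -1.2)
  expect_equal(baseline_gamma(0, 0, scoring_params()), 0)
})

test_that("phylogenetic factor is the normalized mutation count", {
  expect_equal(phylo_factor(3, 4, beta = 10), 11)
  expect_equal(phylo_factor(0, 7, beta = 10), 1)
  expect_equal(phylo_factor(1, 3, beta = 10), 6)
  expect_equal(phylo_factor(0, 1, beta = 10), 1)  # degenerate b
  expect_equal(phylo_factor(0, 0, beta = 10), 1)
  expect_error(phylo_factor(3, 3, beta = 10), "inconsistent")
})

test_that("scaled gamma reduces to baseline at eps = 1", {
  p <- scoring_params()
  expect_equal(phylo_gamma(1, 0.7, 1.5, p), baseline_gamma(0.7, 1.5, p))
  expect_equal(phylo_gamma(11, 1, 0, p), 11)
  expect_equal(phylo_gamma(2, 0.5, 1, scoring_params(phi1 = 0.6)), 0.4)
})

test_that("score_all_pairs fills a consistent table", {
  sim <- rand_struct_instance(3, n_taxa = 6L, L = 12L, n_pairs = 2L)
  cov <- score_all_pairs(sim$aln, sim$tree, scoring_params(beta = 10))
  df <- as.data.frame(cov)
  expect_equal(nrow(df), choose(12, 2))
  # spot-check every scalar against the single-pair operations
  p <- scoring_params(beta = 10)
  for (r in c(1, 10, 40, nrow(df))) {
    i <- df$i[r]; j <- df$j[r]
    expect_equal(df$V[r], conservation_score(sim$aln, i, j, p))
    expect_equal(df$Q[r], penalty_score(sim$aln, i, j))
    mb <- pair_fitch(sim$tree, sim$aln, i, j)
    expect_equal(df$m[r], mb$m)
    expect_equal(df$b[r], mb$b)
    expect_equal(df$eps[r], phylo_factor(mb$m, mb$b, 10))
    expect_equal(df$gamma_p[r], phylo_gamma(df$eps[r], df$V[r], df$Q[r], p))
  }
  # mask: threshold and hairpin separation
  expect_true(all(df$j[df$pairable] - df$i[df$pairable] > 3))
  expect_true(all(df$gamma_p[df$pairable] > p$gamma_t))
})

test_that("identical sequences yield the baseline matrix (eps = 1)", {
  aln <- rna_alignment(c(a = "GGGCAAAAGCCC", b = "GGGCAAAAGCCC",
                         c = "GGGCAAAAGCCC"))
  tr <- read_newick("((a,b),c);")
  cov <- score_all_pairs(aln, tr, scoring_params(beta = 10))
  expect_true(all(cov$eps[upper.tri(cov$eps)] == 1))
  expect_identical(cov$gamma_p, cov$gamma)
})

test_that("bounds, monotonicity and dominance hold on random instances", {
  for (seed in 1:12) {
    sim <- rand_struct_instance(seed, n_taxa = 8L, L = 14L, n_pairs = 3L)
    covs <- lapply(c(0, 5, 10), function(b)
      score_all_pairs(sim$aln, sim$tree, scoring_params(beta = b)))
    ut <- upper.tri(covs[[1]]$eps)
    for (cv in covs) {
      expect_true(all(cv$eps[ut] >= 1))
      expect_true(all(cv$eps[ut] <= 1 + cv$params$beta))
      expect_true(all(cv$m[ut] >= 0))
      expect_true(all(cv$m[ut] <= pmax(cv$b[ut] - 1, 0)))
      # Hamming mode: V >= 0 so the phylogenetic bonus never hurts
      expect_true(all(cv$gamma_p[ut] >= cv$gamma[ut]))
    }
    # gamma_p non-decreasing in beta
    expect_true(all(covs[[2]]$gamma_p[ut] >= covs[[1]]$gamma_p[ut]))
    expect_true(all(covs[[3]]$gamma_p[ut] >= covs[[2]]$gamma_p[ut]))
    # dominance: baseline-pairable implies pairable under gamma_p
    base_mask <- covs[[1]]$pairable
    expect_true(all(covs[[3]]$pairable[base_mask]))
  }
})

test_that("scores are invariant under consistent row permutation", {
  sim <- rand_struct_instance(21, n_taxa = 6L, L = 12L, n_pairs = 2L)
  perm <- c(4, 1, 6, 2, 5, 3)
  aln2 <- rna_alignment(sim$aln$seqs[perm], names = sim$aln$names[perm])
  cov1 <- score_all_pairs(sim$aln, sim$tree, scoring_params(beta = 10))
  cov2 <- score_all_pairs(aln2, sim$tree, scoring_params(beta = 10))
  for (f in c("V", "Q", "gamma", "m", "b", "eps", "gamma_p", "pairable"))
    expect_equal(cov1[[f]], cov2[[f]], info = f)
})

test_that("covariance table writes to TSV with the documented columns", {
  sim <- rand_struct_instance(5, n_taxa = 4L, L = 10L, n_pairs = 1L)
  cov <- score_all_pairs(sim$aln, sim$tree, scoring_params())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cov_tsv(cov, f)
  back <- utils::read.delim(f)
  expect_identical(names(back), c("i", "j", "V", "Q", "gamma", "m", "b",
                                  "eps", "gamma_p", "pairable"))
  expect_equal(nrow(back), choose(10, 2))
})

test_that("the shipped synthetic matrix file matches the generator", {
  f <- system.file("extdata", "ribosum_synthetic.tsv",
                   package = "phylocofold")
  expect_true(nzchar(f))
  expect_equal(read_ribosum(f), synthetic_ribosum())
})
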