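test_that("folding with an all-false mask returns the open chain", {
  aln <- rna_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA"))
  cov <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  expect_equal(sum(cov$pairable), 0L)
  fr <- fold(aln, cov)
  expect_equal(nrow(fr$structure$pairs), 0L)
  expect_equal(fr$energy, 0)
})

test_that("a single hairpin is found and matches exhaustive enumeration", {
  aln <- rna_alignment(c(a = "GGGAAAACCC", b = "GGGAAAACCC"))
  cov <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  fr <- fold(aln, cov)
  bf <- brute_force_fold(aln, cov)
  expect_equal(fr$energy, bf$energy, tolerance = 1e-9)
  expect_true(nrow(fr$structure$pairs) >= 2L)
  expect_equal(serialize_dotbracket(fr$structure),
               serialize_dotbracket(bf$structure))
})

test_that("re-scoring the traced structure reproduces the DP minimum", {
  for (seed in 1:20) {
    sim <- rand_struct_instance(seed)
    cov <- score_all_pairs(sim$aln, sim$tree, scoring_params(beta = 10))
    fr <- fold(sim$aln, cov)
    sc <- score_structure(sim$aln, fr$structure, cov)
    expect_equal(sc$energy, fr$energy, tolerance = 1e-9)
    expect_equal(fr$dp_energy, fr$energy, tolerance = 1e-9)
    # breakdown components sum to the total
    expect_equal(fr$energy_breakdown$loop + fr$energy_breakdown$covariance,
                 fr$energy, tolerance = 1e-12)
  }
})

test_that("hand decomposition of a 3-stack hairpin matches score_structure", {
  aln <- rna_alignment(c(a = "GGGAAAACCC", b = "GGGAAAACCC"))
  cov <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  em <- energy_model()
  st <- rna_structure(10, rbind(c(1, 10), c(2, 9), c(3, 8)))
  # per sequence: hairpin of 4 nt closed by (3,8), two GC/GC stacks
  hp <- em$hairpin_a + em$hairpin_b * log(4 / 3)
  stk <- em$stack["GC", "GC"]
  covsum <- -cov$params$phi2 *
    (cov$gamma_p[1, 10] + cov$gamma_p[2, 9] + cov$gamma_p[3, 8])
  expected <- (2 * (hp + 2 * stk) + covsum) / 2
  expect_equal(score_structure(aln, st, cov, em)$energy, expected)
})

test_that("structures violating the mask or geometry score +Inf", {
  aln <- rna_alignment(c(a = "GGGAAAACCC", b = "GGGAAAACCC"))
  cov <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  # (1, 4) violates the minimum hairpin separation -> unpairable
  st <- rna_structure(10, rbind(c(1, 4)))
  expect_equal(score_structure(aln, st, cov)$energy, Inf)
})

test_that("DP equals the brute-force oracle on random instances, both modes", {
  n_bad <- 0L
  for (seed in 1:40) {
    sim <- rand_struct_instance(seed, n_taxa = 4L,
                                L = sample(c(10L, 12L, 14L), 1L),
                                n_pairs = 2L)
    for (mode in c(FALSE, TRUE)) {
      p <- scoring_params(beta = 10, use_ribosum = mode)
      cov <- score_all_pairs(sim$aln, sim$tree, p)
      fr <- fold(sim$aln, cov)
      bf <- brute_force_fold(sim$aln, cov)
      expect_equal(fr$energy, bf$energy, tolerance = 1e-9,
                   info = paste("seed", seed, "ribosum", mode))
      if (abs(fr$energy - bf$energy) > 1e-9) n_bad <- n_bad + 1L
    }
  }
  expect_equal(n_bad, 0L)
})

test_that("increasing beta never raises the optimal energy (bonus sign)", {
  for (seed in 1:8) {
    sim <- rand_struct_instance(seed, n_taxa = 6L, L = 14L, n_pairs = 3L)
    e <- vapply(c(0, 5, 10), function(b) {
      cov <- score_all_pairs(sim$aln, sim$tree, scoring_params(beta = b))
      fold(sim$aln, cov)$energy
    }, 0)
    expect_true(e[2] <= e[1] + 1e-9 && e[3] <= e[2] + 1e-9,
                info = paste("seed", seed))
  }
})

test_that("all-gap columns never appear in a predicted pair", {
  sim <- rand_struct_instance(13, n_taxa = 4L, L = 12L, n_pairs = 2L)
  m <- sim$aln$mat
  m[, 6] <- "-"  # make an interior column all-gap
  aln <- rna_alignment(apply(m, 1, paste, collapse = ""),
                       names = sim$aln$names)
  cov <- score_all_pairs(aln, sim$tree, scoring_params(beta = 10))
  fr <- fold(aln, cov)
  expect_false(6L %in% c(fr$structure$pairs))
})

test_that("the literal covariance sign flips the pseudo-energy", {
  aln <- rna_alignment(c(a = "GGGAAAACCC", b = "GGGAAAACCC"))
  cov_b <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  cov_l <- score_all_pairs(aln, NULL,
                           scoring_params(beta = 0, cov_sign = "literal"))
  st <- rna_structure(10, rbind(c(3, 8)))
  eb <- score_structure(aln, st, cov_b)
  el <- score_structure(aln, st, cov_l)
  expect_equal(eb$breakdown$covariance, -el$breakdown$covariance)
  expect_equal(eb$breakdown$loop, el$breakdown$loop)
})

test_that("energy model round-trips through its text format", {
  em <- energy_model(Ma = 4.1, Mc = 0.25)
  f <- withr::local_tempfile(fileext = ".par")
  write_energy_model(em, f)
  back <- read_energy_model(f)
  expect_equal(back, em)
  shipped <- read_energy_model(system.file("extdata", "energy_default.par",
                                           package = "phylocofold"))
  expect_equal(shipped, energy_model())
})

test_that("brute force refuses long alignments", {
  aln <- rand_aln(2, 20, seed = 1, gap_prob = 0)
  cov <- score_all_pairs(aln, NULL, scoring_params(beta = 0))
  expect_error(brute_force_fold(aln, cov), "refuses")
})
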