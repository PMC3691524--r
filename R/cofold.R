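#' Phylogeny-aware consensus structure prediction
#'
#' The central fitting function: scores every column pair of the
#' alignment ([score_all_pairs]), boosting covariance by the number of
#' covarying mutations counted on the phylogenetic tree, then folds the
#' consensus minimum-free-energy structure ([fold]).
#'
#' With `beta = 0` the phylogenetic factor is identically 1 and the
#' result is the plain covariance-scored consensus fold; no tree is
#' needed or used.  With `beta > 0` and no tree supplied, a Jukes-Cantor
#' + UPGMA tree is built from the alignment (with a message); for
#' production use supply a tree estimated with a dedicated phylogeny
#' program -- any rooted binary tree works.
#'
#' @param aln an [rna_alignment], or a path to an alignment file
#'   (passed to [read_alignment]).
#' @param tree a rooted binary `ape::phylo`, a path to a Newick file, or
#'   `NULL`.
#' @param params a [scoring_params].
#' @param energy an [energy_model].
#' @param binarize resolve multifurcating input trees instead of
#'   rejecting them.
#' @return an object of class `cofold`: list with `structure`
#'   (an [rna_structure]), `energy` (normalized consensus energy),
#'   `energy_breakdown`, `cov` (the full `cov_matrix`), `tree`,
#'   `params`, `energy_model`, `call`.  Methods: `print`, `summary`,
#'   `plot`.
#' @examples
#' aln <- rna_alignment(c(a = "GGGCAAAAGCCC", b = "GGGCAAAAGCCC",
#'                        c = "GCGCAAAAGCGC", d = "GAGCAAAAGCUC"))
#' fit <- cofold(aln, params = scoring_params(beta = 10))
#' fit
#' summary(fit)
#' @export
cofold <- function(aln, tree = NULL, params = scoring_params(),
                   energy = energy_model(), binarize = FALSE) {
  cl <- match.call()
  if (is.character(aln)) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "rna_alignment"))
  if (is.character(tree)) tree <- read_newick(tree, binarize = binarize)
  if (params$beta > 0) {
    if (is.null(tree)) {
      message("no tree supplied; building a Jukes-Cantor + UPGMA tree ",
              "from the alignment")
      tree <- upgma_tree(distance_matrix(aln))
    }
    tree <- validate_tree(tree, aln, binarize = binarize)
  } else {
    tree <- NULL
  }
  cov <- score_all_pairs(aln, tree, params)
  fr <- fold(aln, cov, energy)
  structure(list(structure = fr$structure, energy = fr$energy,
                 energy_breakdown = fr$energy_breakdown,
                 cov = cov, tree = tree, params = params,
                 energy_model = energy, aln = aln, call = cl),
            class = "cofold")
}

#' @export
print.cofold <- function(x, ...) {
  cat("Consensus structure (", nrow(x$structure$pairs), " base pairs, ",
      "beta = ", x$params$beta,
      if (x$params$use_ribosum) ", RIBOSUM" else ", Hamming",
      " scoring):\n", sep = "")
  cat("  ", serialize_dotbracket(x$structure), "\n", sep = "")
  cat(sprintf("  energy = %.4f per sequence\n", x$energy))
  invisible(x)
}

#' @export
summary.cofold <- function(object, ...) {
  x <- object
  df <- as.data.frame(x$cov)
  helix <- df[df$pairable, ]
  pr <- x$structure$pairs
  eps_pred <- if (nrow(pr)) x$cov$eps[pr] else numeric(0)
  out <- list(
    n_seq = x$cov$N, L = x$cov$L, beta = x$params$beta,
    mode = if (x$params$use_ribosum) "RIBOSUM" else "Hamming",
    mpi = pairwise_identity(x$aln),
    n_pairs = nrow(pr),
    n_pairable = sum(df$pairable),
    energy = x$energy,
    breakdown = x$energy_breakdown,
    mean_eps_predicted = if (length(eps_pred)) mean(eps_pred) else NA_real_,
    structure = serialize_dotbracket(x$structure))
  class(out) <- "summary.cofold"
  out
}

#' @export
print.summary.cofold <- function(x, ...) {
  cat("Consensus folding summary\n")
  cat(sprintf("  alignment: %d sequences x %d columns (MPI %.1f%%)\n",
              x$n_seq, x$L, x$mpi))
  cat(sprintf("  scoring: %s mode, beta = %g\n", x$mode, x$beta))
  cat(sprintf("  pairable column pairs: %d; predicted base pairs: %d\n",
              x$n_pairable, x$n_pairs))
  if (!is.na(x$mean_eps_predicted))
    cat(sprintf("  mean phylogenetic factor at predicted pairs: %.3f\n",
                x$mean_eps_predicted))
  cat(sprintf("  energy: %.4f per sequence (loop %.4f, covariance %.4f)\n",
              x$energy, x$breakdown$loop, x$breakdown$covariance))
  cat("  ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Arc diagram of a predicted consensus structure
#'
#' Base-paired columns are joined by semicircular arcs above the
#' sequence line; arc colour encodes the phylogenetic factor `eps` of
#' the pair (darker = more covarying mutations on the tree).
#'
#' @param x a `cofold` fit.
#' @param ... passed to [graphics::plot].
#' @export
plot.cofold <- function(x, ...) {
  L <- x$structure$length
  pr <- x$structure$pairs
  graphics::plot(NA, xlim = c(1, L), ylim = c(0, max(2, L / 2)),
                 xlab = "alignment column", ylab = "", yaxt = "n",
                 bty = "n", ...)
  graphics::abline(h = 0, col = "grey60")
  if (nrow(pr)) {
    eps <- x$cov$eps[pr]
    rng <- range(eps)
    shade <- if (diff(rng) > 0) (eps - rng[1]) / diff(rng) else
      rep(0, length(eps))
    cols <- grDevices::grey(0.7 - 0.6 * shade)
    th <- seq(0, pi, length.out = 60)
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      r <- (j - i) / 2
      graphics::lines((i + j) / 2 + r * cos(th), r * sin(th),
                      col = cols[k], lwd = 2)
    }
  }
  invisible(x)
}
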