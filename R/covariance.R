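#' Scoring parameters for covariance computation
#'
#' @param beta non-negative scale for the phylogenetic factor
#'   `eps = 1 + beta * m / (b - 1)`; `beta = 0` recovers the plain
#'   (phylogeny-free) covariance score.  Default 10.
#' @param phi1 weight of the penalty score in `gamma = V - phi1 * Q`;
#'   defaults to 1 in Hamming mode and 0.6 in RIBOSUM mode.
#' @param phi2 weight of the covariance pseudo-energy at a closing pair
#'   during folding; defaults to 1 in Hamming mode and 0.5 in RIBOSUM
#'   mode.
#' @param gamma_t pairing threshold: columns `(i, j)` are candidate
#'   pairing columns when their covariance score exceeds `gamma_t`.
#'   Default -2.
#' @param use_ribosum score conservation with a RIBOSUM-style base-pair
#'   substitution matrix instead of Hamming distances.
#' @param ribosum 16 x 16 matrix indexed by ordered dinucleotides
#'   (`AA`, `AC`, ..., `UU`); defaults to the bundled synthetic matrix
#'   when `use_ribosum = TRUE`.
#' @param min_hairpin minimum number of alignment columns enclosed by a
#'   pair (steric hairpin constraint); pairs with `j - i <= min_hairpin`
#'   are never allowed.  Default 3.
#' @param cov_sign `"bonus"` (default): the covariance term enters the
#'   folding energy as `-phi2 * gamma_p`, so conserved/covarying pairs
#'   lower the energy; `"literal"`: `+phi2 * gamma_p`.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(beta = 10, phi1 = NULL, phi2 = NULL,
                           gamma_t = -2, use_ribosum = FALSE,
                           ribosum = NULL, min_hairpin = 3L,
                           cov_sign = c("bonus", "literal")) {
  cov_sign <- match.arg(cov_sign)
  if (beta < 0) stop("beta must be >= 0")
  if (!is.finite(gamma_t)) stop("gamma_t must be finite")
  if (is.null(phi1)) phi1 <- if (use_ribosum) 0.6 else 1
  if (is.null(phi2)) phi2 <- if (use_ribosum) 0.5 else 1
  if (use_ribosum && is.null(ribosum)) ribosum <- synthetic_ribosum()
  if (use_ribosum) {
    stopifnot(is.matrix(ribosum), all(dim(ribosum) == 16L))
    dn <- dinuc_names()
    if (is.null(dimnames(ribosum))) dimnames(ribosum) <- list(dn, dn)
    ribosum <- ribosum[dn, dn]
  }
  structure(list(beta = beta, phi1 = phi1, phi2 = phi2, gamma_t = gamma_t,
                 use_ribosum = use_ribosum, ribosum = ribosum,
                 min_hairpin = as.integer(min_hairpin),
                 cov_sign = cov_sign),
            class = "scoring_params")
}

dinuc_names <- function() {
  b <- c("A", "C", "G", "U")
  as.vector(t(outer(b, b, paste0)))
}

#' Synthetic RIBOSUM-style base-pair substitution matrix
#'
#' A deterministic stand-in with the qualitative structure of a RIBOSUM
#' log-odds matrix: conserved canonical pairs score positively,
#' compensatory double substitutions between canonical pairs score
#' highest, single substitutions in between, and any dinucleotide that
#' is not a canonical pair scores negatively.  It is *synthetic* -- not
#' estimated from ribosomal alignments; substitute a genuine RIBOSUM
#' matrix via [read_ribosum] for production scoring.
#'
#' @return a symmetric 16 x 16 matrix with dinucleotide dimnames.
#' @export
synthetic_ribosum <- function() {
  dn <- dinuc_names()
  R <- matrix(-4, 16, 16, dimnames = list(dn, dn))
  canon <- CANONICAL_PAIRS
  for (p in canon) for (q in canon) {
    ndiff <- sum(strsplit(p, "")[[1L]] != strsplit(q, "")[[1L]])
    R[p, q] <- c(2, 1.2, 3.5)[ndiff + 1L]
  }
  R[!(rownames(R) %in% canon), ] <- -4
  R[, !(colnames(R) %in% canon)] <- -4
  diag(R)[!(dn %in% canon)] <- -2
  R
}

#' Read a base-pair substitution matrix from TSV
#'
#' Expects a tab-separated 16 x 16 matrix with ordered-dinucleotide row
#' and column names (`AA` ... `UU`); `#` lines are comments.
#'
#' @param path file path.
#' @return a 16 x 16 numeric matrix.
#' @export
read_ribosum <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   sep = "\t", comment.char = "#",
                                   check.names = FALSE))
  dn <- dinuc_names()
  if (!setequal(rownames(m), dn) || !setequal(colnames(m), dn))
    stop("matrix must be indexed by the 16 ordered dinucleotides AA..UU")
  m[dn, dn]
}

#' Conservation score of a column pair
#'
#' Sum over all unordered sequence pairs, divided by `N`, of a
#' similarity term contributed only when both sequences show a canonical
#' base pair at columns `(i, j)`: in Hamming mode the term is
#' `h(s_ik, s_il) + h(s_jk, s_jl)` (0, 1 or 2 -- base pairs without,
#' with one, or with two mutations); in RIBOSUM mode it is the matrix
#' entry for the two ordered dinucleotides.
#'
#' @param aln an [rna_alignment].
#' @param i,j column indices, `i < j`.
#' @param params a [scoring_params].
#' @return the conservation score `V`.
#' @export
conservation_score <- function(aln, i, j, params = scoring_params()) {
  check_cols(aln, i, j)
  x <- aln$mat[, i]; y <- aln$mat[, j]
  codes <- pair_codes(x, y)
  S <- which(codes > 0L)
  N <- nrow(aln$mat)
  if (length(S) < 2L) return(0)
  if (!params$use_ribosum) {
    (count_diff_pairs(x[S]) + count_diff_pairs(y[S])) / N
  } else {
    di <- paste0(x[S], y[S])
    cnt <- table(factor(di, levels = dinuc_names()))
    cnt <- as.numeric(cnt)
    R <- params$ribosum
    tot <- (drop(cnt %*% R %*% cnt) - sum(diag(R) * cnt)) / 2
    tot / N
  }
}

# number of unordered pairs (k, l) with x_k != x_l
count_diff_pairs <- function(x) {
  n <- length(x)
  cnt <- table(x)
  (n * (n - 1) - sum(cnt * (cnt - 1))) / 2
}

#' Penalty score of a column pair
#'
#' Per-sequence penalty for symbols that cannot form a base pair:
#' 0 for a canonical pair, 0.25 when both positions are gaps, 1
#' otherwise (including ambiguity codes and one-sided gaps).
#'
#' @inheritParams conservation_score
#' @return the penalty score `Q`.
#' @export
penalty_score <- function(aln, i, j) {
  check_cols(aln, i, j)
  x <- aln$mat[, i]; y <- aln$mat[, j]
  codes <- pair_codes(x, y)
  sum(ifelse(codes > 0L, 0, ifelse(x == "-" & y == "-", 0.25, 1)))
}

check_cols <- function(aln, i, j) {
  stopifnot(inherits(aln, "rna_alignment"))
  L <- ncol(aln$mat)
  if (i >= j) stop("need i < j, got i = ", i, ", j = ", j)
  if (i < 1L || j > L) stop("column index out of range 1..", L)
  invisible(TRUE)
}

#' Baseline covariance score
#'
#' `gamma = V - phi1 * Q`: conservation reward minus weighted
#' non-pairing penalty.
#'
#' @param V conservation score.
#' @param Q penalty score.
#' @param params a [scoring_params].
#' @return the covariance score.
#' @export
baseline_gamma <- function(V, Q, params = scoring_params()) {
  V - params$phi1 * Q
}

#' Phylogenetic factor from a parsimony mutation count
#'
#' `eps = 1 + beta * m / (b - 1)` for `b >= 2`; the normalizer `b - 1`
#' is the maximum number of pair-switch mutations a tree with `b`
#' pair-carrying leaves can require, so `eps` lies in `[1, 1 + beta]`.
#' For `b <= 1` the normalization is undefined but `m` is necessarily 0,
#' and `eps = 1` (no bonus) is returned.
#'
#' @param m covarying-mutation count on the tree.
#' @param b number of leaves carrying a canonical pair.
#' @param beta non-negative scale parameter.
#' @return the factor `eps`.
#' @export
phylo_factor <- function(m, b, beta = 10) {
  m <- as.integer(m); b <- as.integer(b)
  if (m < 0 || m > max(b - 1L, 0L))
    stop("inconsistent parsimony counts: m = ", m, ", b = ", b)
  if (b <= 1L) return(1)
  1 + beta * m / (b - 1)
}

#' Phylogeny-scaled covariance score
#'
#' `gamma_p = eps * V - phi1 * Q`.  With `eps = 1` (no covarying
#' mutations, or `beta = 0`) this reduces exactly to [baseline_gamma].
#'
#' @param eps phylogenetic factor from [phylo_factor].
#' @inheritParams baseline_gamma
#' @return the scaled covariance score.
#' @export
phylo_gamma <- function(eps, V, Q, params = scoring_params()) {
  eps * V - params$phi1 * Q
}

#' Score every column pair of an alignment
#'
#' Computes the full per-column-pair score table: conservation `V`,
#' penalty `Q`, baseline covariance `gamma`, the parsimony counts
#' `(m, b)` from the gap-aware Fitch pass, the phylogenetic factor
#' `eps`, the scaled score `gamma_p`, and the pairing mask
#' (`gamma_p > gamma_t` and `j - i > min_hairpin`).
#'
#' @param aln an [rna_alignment].
#' @param tree a rooted binary `ape::phylo` over the alignment's
#'   sequences; may be `NULL` when `beta = 0` (the Fitch pass is skipped
#'   and `eps` is identically 1).
#' @param params a [scoring_params].
#' @return an object of class `cov_matrix`: a list of upper-triangular
#'   `L x L` matrices `V, Q, gamma, m, b, eps, gamma_p, pairable` plus
#'   the parameters used.
#' @export
score_all_pairs <- function(aln, tree = NULL, params = scoring_params()) {
  stopifnot(inherits(aln, "rna_alignment"))
  L <- ncol(aln$mat)
  N <- nrow(aln$mat)
  if (params$beta > 0 && is.null(tree))
    stop("a tree is required when beta > 0 (pass beta = 0 for the ",
         "phylogeny-free score)")
  if (!is.null(tree) && is.null(attr(tree, "row_of_tip")))
    tree <- validate_tree(tree, aln)
  V <- Q <- gam <- eps <- gam_p <- matrix(NA_real_, L, L)
  have_tree <- !is.null(tree)
  if (have_tree) {
    mb <- pair_fitch_all(tree, aln)
    m_tab <- mb$m; b_tab <- mb$b
  } else {
    m_tab <- b_tab <- matrix(NA_integer_, L, L)
  }
  base_idx <- matrix(match(aln$mat, c("A", "C", "G", "U")), nrow = N)
  gap <- aln$mat == "-"
  R <- params$ribosum
  for (i in seq_len(L - 1L)) {
    xi <- base_idx[, i]
    for (j in (i + 1L):L) {
      yj <- base_idx[, j]
      ok <- !is.na(xi) & !is.na(yj)
      codes <- integer(N)
      if (any(ok)) codes[ok] <- .pair_code_table[cbind(xi[ok], yj[ok])]
      S <- codes > 0L
      nS <- sum(S)
      # conservation
      v <- 0
      if (nS >= 2L) {
        if (!params$use_ribosum) {
          v <- (count_diff_pairs(xi[S]) + count_diff_pairs(yj[S])) / N
        } else {
          di <- (xi[S] - 1L) * 4L + yj[S]
          cnt <- tabulate(di, nbins = 16L)
          v <- ((drop(cnt %*% R %*% cnt) - sum(diag(R) * cnt)) / 2) / N
        }
      }
      V[i, j] <- v
      # penalty
      Q[i, j] <- sum(ifelse(S, 0, ifelse(gap[, i] & gap[, j], 0.25, 1)))
      gam[i, j] <- v - params$phi1 * Q[i, j]
      if (have_tree) {
        b <- b_tab[i, j]
        eps[i, j] <- if (b <= 1L) 1 else
          1 + params$beta * m_tab[i, j] / (b - 1)
      } else {
        eps[i, j] <- 1
      }
      gam_p[i, j] <- eps[i, j] * v - params$phi1 * Q[i, j]
    }
  }
  sep_ok <- outer(seq_len(L), seq_len(L),
                  function(a, b) b - a > params$min_hairpin)
  pairable <- !is.na(gam_p) & gam_p > params$gamma_t & sep_ok
  structure(list(L = L, N = N, V = V, Q = Q, gamma = gam,
                 m = m_tab, b = b_tab, eps = eps, gamma_p = gam_p,
                 pairable = pairable, params = params),
            class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat("Covariance score matrix: L = ", x$L, ", N = ", x$N,
      ", beta = ", x$params$beta,
      if (x$params$use_ribosum) ", RIBOSUM mode" else ", Hamming mode",
      "\n  pairable column pairs: ", sum(x$pairable, na.rm = TRUE), "\n",
      sep = "")
  invisible(x)
}

#' Covariance table as a data frame
#'
#' One row per column pair `(i, j)`, `i < j`, with all scores and the
#' pairing mask; 1-based indices.
#'
#' @param x a `cov_matrix`.
#' @param ... unused.
#' @return a data frame with columns
#'   `i, j, V, Q, gamma, m, b, eps, gamma_p, pairable`.
#' @export
as.data.frame.cov_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$V), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  data.frame(i = ut[, 1], j = ut[, 2],
             V = x$V[ut], Q = x$Q[ut], gamma = x$gamma[ut],
             m = x$m[ut], b = x$b[ut], eps = x$eps[ut],
             gamma_p = x$gamma_p[ut], pairable = x$pairable[ut])
}

#' Write the covariance table as TSV
#'
#' @param cov a `cov_matrix` from [score_all_pairs].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cov_tsv <- function(cov, path) {
  utils::write.table(as.data.frame(cov), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
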