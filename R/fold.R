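# Per-alignment precomputation shared by the DP and the re-scorer:
# base indices, pair-type codes on demand, and cumulative non-gap counts
# so per-sequence loop sizes in degapped coordinates are O(1).
fold_context <- function(aln, em) {
  mat <- aln$mat
  N <- nrow(mat); L <- ncol(mat)
  base_idx <- matrix(match(mat, c("A", "C", "G", "U")), nrow = N)
  nongap <- !is.na(base_idx) | (mat != "-")  # non-gap chars incl. ambiguity
  cng <- cbind(0L, t(apply(nongap, 1L, cumsum)))  # cng[s, i+1] = # in 1..i
  list(N = N, L = L, base_idx = base_idx, cng = cng, em = em)
}

# pair-type codes (0 = cannot pair) for all sequences at columns (i, j)
ctx_pt <- function(ctx, i, j) {
  xi <- ctx$base_idx[, i]; yj <- ctx$base_idx[, j]
  out <- integer(ctx$N)
  ok <- !is.na(xi) & !is.na(yj)
  if (any(ok)) out[ok] <- .pair_code_table[cbind(xi[ok], yj[ok])]
  out
}

# sum over sequences of hairpin energies for closing columns (i, j)
hairpin_sum <- function(ctx, i, j) {
  pt <- ctx_pt(ctx, i, j)
  s <- which(pt > 0L)
  if (!length(s)) return(0)
  n <- ctx$cng[s, j] - ctx$cng[s, i + 1L]  # non-gaps strictly inside
  em <- ctx$em
  sum(ifelse(n < 3, em$hairpin_short,
             em$hairpin_a + em$hairpin_b * log(pmax(n, 3) / 3)))
}

# sum over sequences of stack/interior energies for outer (i, j), inner (p, q)
interior_sum <- function(ctx, i, j, p, q) {
  pt_out <- ctx_pt(ctx, i, j)
  pt_in <- ctx_pt(ctx, p, q)
  s <- which(pt_out > 0L & pt_in > 0L)
  if (!length(s)) return(0)
  n1 <- ctx$cng[s, p] - ctx$cng[s, i + 1L]
  n2 <- ctx$cng[s, j] - ctx$cng[s, q + 1L]
  ntot <- n1 + n2
  em <- ctx$em
  e <- numeric(length(s))
  stk <- ntot == 0L
  if (any(stk))
    e[stk] <- em$stack[cbind(pt_out[s][stk], pt_in[s][stk])]
  if (any(!stk))
    e[!stk] <- em$interior_a + em$interior_b * log(ntot[!stk])
  sum(e)
}

# covariance pseudo-energy at a closing pair
cov_term <- function(cov, i, j) {
  sgn <- if (cov$params$cov_sign == "literal") 1 else -1
  sgn * cov$params$phi2 * cov$gamma_p[i, j]
}

#' Consensus minimum-free-energy folding of an alignment
#'
#' Fills the four interval tables of the consensus-folding recursion --
#' unconstrained (`F`), closed by a pair (`C`), multiloop component
#' (`FM`), and single-branch multiloop component (`FM1`) -- over all
#' column intervals.  A pair `(i, j)` may close a structure only where
#' the covariance mask allows it; the closing contribution is the summed
#' per-sequence loop energy plus the covariance pseudo-energy
#' (`-phi2 * gamma_p` by default, so covarying columns are favoured).
#' Traceback yields a non-crossing structure attaining the minimum; the
#' reported energy is the independent re-scoring of that structure
#' ([score_structure]), normalized per sequence.
#'
#' @param aln an [rna_alignment].
#' @param cov a `cov_matrix` from [score_all_pairs] computed on `aln`.
#' @param em an [energy_model].
#' @return an object of class `fold_result`: list with `structure`
#'   (an [rna_structure]), `energy` (normalized), `energy_breakdown`
#'   (loop and covariance totals, normalized), `dp_energy`.
#' @export
fold <- function(aln, cov, em = energy_model()) {
  stopifnot(inherits(aln, "rna_alignment"), inherits(cov, "cov_matrix"))
  L <- ncol(aln$mat); N <- nrow(aln$mat)
  if (cov$L != L) stop("covariance matrix does not match alignment length")
  ctx <- fold_context(aln, em)
  params <- cov$params
  mh <- params$min_hairpin
  if (L < mh + 2L || !any(cov$pairable)) {
    st <- rna_structure(L)
    sc <- score_structure(aln, st, cov, em)
    return(new_fold_result(st, sc, 0))
  }
  pairable <- cov$pairable
  nMa <- N * em$Ma; nMb <- N * em$Mb; nMc <- N * em$Mc
  C <- Fm <- FM <- FM1 <- matrix(Inf, L, L)
  diag(Fm) <- 0  # a single unpaired column is free
  covt <- matrix(0, L, L)
  # F over empty regions is 0 (unpaired bases are free)
  fget <- function(M, i, j) if (i > j) 0 else M[i, j]
  for (span in 1:(L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      if (pairable[i, j]) {
        best <- hairpin_sum(ctx, i, j)
        # interior / stack
        pmax_ <- min(i + 1L + em$max_interior, j - 2L)
        if (pmax_ >= i + 1L) for (p in (i + 1L):pmax_) {
          left <- p - i - 1L
          qmin <- max(p + 1L, j - 1L - (em$max_interior - left))
          if (qmin > j - 1L) next
          for (q in qmin:(j - 1L)) {
            if (!pairable[p, q] || !is.finite(C[p, q])) next
            cand <- interior_sum(ctx, i, j, p, q) + C[p, q]
            if (cand < best) best <- cand
          }
        }
        # multiloop: >= 2 branches strictly inside
        if (j - i >= 5L) for (p in (i + 2L):(j - 3L)) {
          if (!is.finite(FM[i + 1L, p]) || !is.finite(FM1[p + 1L, j - 1L]))
            next
          cand <- FM[i + 1L, p] + FM1[p + 1L, j - 1L] + nMa
          if (cand < best) best <- cand
        }
        covt[i, j] <- cov_term(cov, i, j)
        C[i, j] <- covt[i, j] + best
      }
      # FM1: exactly one branch starting at i, optional unpaired tail
      v <- if (j - 1L >= i) FM1[i, j - 1L] + nMc else Inf
      if (is.finite(C[i, j])) v <- min(v, C[i, j] + nMb)
      FM1[i, j] <- v
      # FM: >= 1 branch
      v <- FM1[i, j]
      if (i + 1L <= j) v <- min(v, FM[i + 1L, j] + nMc)
      if (j - i >= 2L) for (p in (i + 1L):(j - 1L)) {
        if (!is.finite(C[i, p]) || !is.finite(FM[p + 1L, j])) next
        v <- min(v, C[i, p] + nMb + FM[p + 1L, j])
      }
      FM[i, j] <- v
      # F: unconstrained
      v <- fget(Fm, i + 1L, j)
      for (k in (i + 1L):j) {
        if (!is.finite(C[i, k])) next
        v <- min(v, C[i, k] + fget(Fm, k + 1L, j))
      }
      Fm[i, j] <- v
    }
  }
  pairs <- trace_F(1L, L, ctx, cov, em, C, Fm, FM, FM1, covt)
  st <- rna_structure(L, pairs)
  sc <- score_structure(aln, st, cov, em)
  dp <- Fm[1L, L] / N
  if (is.finite(sc$energy) && abs(dp - sc$energy) > 1e-6)
    stop("internal error: traceback energy ", sc$energy,
         " does not reproduce DP minimum ", dp)
  new_fold_result(st, sc, dp)
}

new_fold_result <- function(st, sc, dp) {
  structure(list(structure = st, energy = sc$energy,
                 energy_breakdown = sc$breakdown, dp_energy = dp),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(serialize_dotbracket(x$structure), "\n", sep = "")
  cat(sprintf("energy = %.4f per sequence (loop %.4f, covariance %.4f)\n",
              x$energy, x$energy_breakdown$loop,
              x$energy_breakdown$covariance))
  invisible(x)
}

.trace_eps <- 1e-9

trace_F <- function(i, j, ctx, cov, em, C, Fm, FM, FM1, covt) {
  pairs <- list()
  while (i <= j) {
    v <- Fm[i, j]
    if (!is.finite(v) || i >= j) break
    if (i + 1L <= j && abs((if (i + 1L > j) 0 else Fm[i + 1L, j]) - v) <=
        .trace_eps) { i <- i + 1L; next }
    hit <- FALSE
    for (k in (i + 1L):j) {
      if (!is.finite(C[i, k])) next
      rest <- if (k + 1L > j) 0 else Fm[k + 1L, j]
      if (abs(C[i, k] + rest - v) <= .trace_eps) {
        pairs <- c(pairs, trace_C(i, k, ctx, cov, em, C, Fm, FM, FM1, covt))
        i <- k + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("internal error: traceback failed at F(", i, ",", j,
                   ")")
  }
  pairs
}

trace_C <- function(i, j, ctx, cov, em, C, Fm, FM, FM1, covt) {
  N <- ctx$N
  pairs <- list(c(i, j))
  inner <- C[i, j] - covt[i, j]
  if (abs(hairpin_sum(ctx, i, j) - inner) <= .trace_eps) return(pairs)
  pmax_ <- min(i + 1L + em$max_interior, j - 2L)
  if (pmax_ >= i + 1L) for (p in (i + 1L):pmax_) {
    left <- p - i - 1L
    qmin <- max(p + 1L, j - 1L - (em$max_interior - left))
    if (qmin > j - 1L) next
    for (q in qmin:(j - 1L)) {
      if (!cov$pairable[p, q] || !is.finite(C[p, q])) next
      if (abs(interior_sum(ctx, i, j, p, q) + C[p, q] - inner) <=
          .trace_eps)
        return(c(pairs, trace_C(p, q, ctx, cov, em, C, Fm, FM, FM1, covt)))
    }
  }
  if (j - i >= 5L) for (p in (i + 2L):(j - 3L)) {
    if (!is.finite(FM[i + 1L, p]) || !is.finite(FM1[p + 1L, j - 1L])) next
    if (abs(FM[i + 1L, p] + FM1[p + 1L, j - 1L] + N * em$Ma - inner) <=
        .trace_eps)
      return(c(pairs,
               trace_FM(i + 1L, p, ctx, cov, em, C, Fm, FM, FM1, covt),
               trace_FM1(p + 1L, j - 1L, ctx, cov, em, C, Fm, FM, FM1,
                         covt)))
  }
  stop("internal error: traceback failed at C(", i, ",", j, ")")
}

trace_FM <- function(i, j, ctx, cov, em, C, Fm, FM, FM1, covt) {
  N <- ctx$N
  v <- FM[i, j]
  if (i + 1L <= j && is.finite(FM[i + 1L, j]) &&
      abs(FM[i + 1L, j] + N * em$Mc - v) <= .trace_eps)
    return(trace_FM(i + 1L, j, ctx, cov, em, C, Fm, FM, FM1, covt))
  if (j - i >= 2L) for (p in (i + 1L):(j - 1L)) {
    if (!is.finite(C[i, p]) || !is.finite(FM[p + 1L, j])) next
    if (abs(C[i, p] + N * em$Mb + FM[p + 1L, j] - v) <= .trace_eps)
      return(c(trace_C(i, p, ctx, cov, em, C, Fm, FM, FM1, covt),
               trace_FM(p + 1L, j, ctx, cov, em, C, Fm, FM, FM1, covt)))
  }
  if (is.finite(FM1[i, j]) && abs(FM1[i, j] - v) <= .trace_eps)
    return(trace_FM1(i, j, ctx, cov, em, C, Fm, FM, FM1, covt))
  stop("internal error: traceback failed at FM(", i, ",", j, ")")
}

trace_FM1 <- function(i, j, ctx, cov, em, C, Fm, FM, FM1, covt) {
  N <- ctx$N
  v <- FM1[i, j]
  if (is.finite(C[i, j]) && abs(C[i, j] + N * em$Mb - v) <= .trace_eps)
    return(trace_C(i, j, ctx, cov, em, C, Fm, FM, FM1, covt))
  if (j - 1L >= i && is.finite(FM1[i, j - 1L]) &&
      abs(FM1[i, j - 1L] + N * em$Mc - v) <= .trace_eps)
    return(trace_FM1(i, j - 1L, ctx, cov, em, C, Fm, FM, FM1, covt))
  stop("internal error: traceback failed at FM1(", i, ",", j, ")")
}

#' Re-score a structure under the consensus energy model
#'
#' Decomposes the structure into hairpin, stack/interior, multiloop and
#' exterior loops and sums the same per-sequence loop energies and
#' covariance pseudo-energies the folding recursion uses, normalized by
#' the number of sequences.  This scorer is shared by the traceback
#' consistency check and the brute-force oracle, which makes oracle
#' comparisons exact.
#'
#' Structures containing a pair the covariance mask forbids, or an
#' interior loop wider than the model allows, score `+Inf`.
#'
#' @param aln an [rna_alignment].
#' @param st an [rna_structure] of the alignment's length.
#' @param cov a `cov_matrix` from [score_all_pairs].
#' @param em an [energy_model].
#' @return a list with `energy` (normalized total) and `breakdown`
#'   (list of normalized `loop` and `covariance` components).
#' @export
score_structure <- function(aln, st, cov, em = energy_model()) {
  stopifnot(inherits(aln, "rna_alignment"), inherits(st, "rna_structure"))
  L <- ncol(aln$mat); N <- nrow(aln$mat)
  if (st$length != L) stop("structure length does not match alignment")
  ctx <- fold_context(aln, em)
  pairs <- st$pairs
  if (!nrow(pairs))
    return(list(energy = 0, breakdown = list(loop = 0, covariance = 0)))
  if (any(!cov$pairable[pairs]))
    return(list(energy = Inf, breakdown = list(loop = Inf, covariance = 0)))
  partner <- integer(L)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  children_of <- function(i, j) {  # direct children pairs inside (i, j)
    out <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (partner[k] > k) {
        out[[length(out) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    out
  }
  loop_e <- 0
  cov_e <- 0
  # exterior "loop": no energy; walk each closing pair
  stack_ <- children_of(0L, L + 1L)
  while (length(stack_)) {
    pr <- stack_[[1L]]; stack_ <- stack_[-1L]
    i <- pr[1L]; j <- pr[2L]
    cov_e <- cov_e + cov_term(cov, i, j)
    ch <- children_of(i, j)
    if (length(ch) == 0L) {
      loop_e <- loop_e + hairpin_sum(ctx, i, j)
    } else if (length(ch) == 1L) {
      p <- ch[[1L]][1L]; q <- ch[[1L]][2L]
      if ((p - i - 1L) + (j - q - 1L) > em$max_interior)
        return(list(energy = Inf,
                    breakdown = list(loop = Inf, covariance = 0)))
      loop_e <- loop_e + interior_sum(ctx, i, j, p, q)
    } else {
      unpaired <- (j - i - 1L) -
        sum(vapply(ch, function(z) z[2L] - z[1L] + 1L, 0L))
      loop_e <- loop_e +
        N * (em$Ma + em$Mb * length(ch) + em$Mc * unpaired)
    }
    stack_ <- c(stack_, ch)
  }
  list(energy = (loop_e + cov_e) / N,
       breakdown = list(loop = loop_e / N, covariance = cov_e / N))
}

#' Brute-force folding oracle
#'
#' Enumerates every non-crossing, endpoint-disjoint subset of the
#' mask-allowed candidate pairs, scores each with [score_structure], and
#' returns the minimum.  Ties are broken toward fewer pairs, then the
#' lexicographically smallest pair list.  Exponential: refuses
#' alignments longer than `max_len` columns.
#'
#' @inheritParams fold
#' @param max_len refusal threshold on alignment length (default 16).
#' @return a `fold_result` (with `dp_energy = NA`).
#' @export
brute_force_fold <- function(aln, cov, em = energy_model(),
                             max_len = 16L) {
  L <- ncol(aln$mat)
  if (L > max_len)
    stop("brute_force_fold refuses L = ", L, " > max_len = ", max_len)
  cand <- which(cov$pairable, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  nc <- nrow(cand)
  best <- list(energy = Inf, pairs = NULL, npairs = Inf, key = "")
  consider <- function(sel) {
    st <- rna_structure(L, cand[sel, , drop = FALSE])
    sc <- score_structure(aln, st, cov, em)
    key <- paste(t(st$pairs), collapse = ",")
    better <- sc$energy < best$energy ||
      (sc$energy == best$energy &&
         (nrow(st$pairs) < best$npairs ||
            (nrow(st$pairs) == best$npairs && key < best$key)))
    if (better)
      best <<- list(energy = sc$energy, st = st, sc = sc,
                    npairs = nrow(st$pairs), key = key)
  }
  compatible <- function(a, b) {  # pairs a, b as (i, j) rows
    if (length(intersect(c(a), c(b)))) return(FALSE)
    i <- a[1]; j <- a[2]; k <- b[1]; l <- b[2]
    if (i > k) { t <- a; a <- b; b <- t; i <- a[1]; j <- a[2]
                 k <- b[1]; l <- b[2] }
    (j < k) || (l < j)
  }
  recurse <- function(idx, sel) {
    if (idx > nc) { consider(sel); return(invisible()) }
    ok <- TRUE
    for (s in sel) if (!compatible(cand[s, ], cand[idx, ])) { ok <- FALSE
      break }
    if (ok) recurse(idx + 1L, c(sel, idx))
    recurse(idx + 1L, sel)
  }
  recurse(1L, integer(0))
  new_fold_result(best$st, best$sc, NA_real_)
}
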