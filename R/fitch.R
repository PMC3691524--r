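# The six canonical base pairs, in fixed order; code 0 is the gap/non-pair
# sentinel used by the gap-aware pass.
CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

# 5x5 lookup (A,C,G,U,-) -> pair code 1..6 or 0
.pair_code_table <- local({
  b <- c("A", "C", "G", "U", "-")
  m <- matrix(0L, 5, 5, dimnames = list(b, b))
  for (k in seq_along(CANONICAL_PAIRS)) {
    p <- strsplit(CANONICAL_PAIRS[k], "")[[1L]]
    m[p[1L], p[2L]] <- k
  }
  m
})

# pair codes for character vectors x (column i) and y (column j);
# anything outside A/C/G/U (gaps, ambiguity codes) cannot pair -> 0
pair_codes <- function(x, y) {
  xi <- match(x, c("A", "C", "G", "U"))
  yi <- match(y, c("A", "C", "G", "U"))
  out <- integer(length(x))
  ok <- !is.na(xi) & !is.na(yi)
  out[ok] <- .pair_code_table[cbind(xi[ok], yi[ok])]
  out
}

#' Forward Fitch pass on a rooted binary tree
#'
#' Bottom-up small-parsimony pass: each leaf starts with its observed
#' label; at an internal node the label set is the intersection of the
#' children's sets when non-empty (no mutation charged), otherwise their
#' union with one mutation charged.  The root's accumulated count is the
#' minimum number of mutations over all internal labelings; only this
#' forward phase is needed since internal labels themselves are not of
#' interest.
#'
#' @param tree a rooted binary `ape::phylo` tree.
#' @param leaf_labels character vector of single-symbol labels, named by
#'   tip label (or unnamed, in tip order).
#' @return a list with `labels` (sorted character vector: the root's
#'   label set) and `cost` (integer mutation count).
#' @export
fitch_forward <- function(tree, leaf_labels) {
  topo <- tree_topology(tree)
  if (!is.null(names(leaf_labels))) {
    miss <- setdiff(tree$tip.label, names(leaf_labels))
    if (length(miss)) stop("unlabeled leaves: ", paste(miss, collapse = ", "))
    leaf_labels <- leaf_labels[tree$tip.label]
  } else if (length(leaf_labels) != topo$ntip) {
    stop("need one label per leaf")
  }
  if (anyNA(leaf_labels)) stop("unlabeled leaf (NA label)")
  alphabet <- sort(unique(leaf_labels))
  if (length(alphabet) > 30L) stop("alphabet too large for bitmask Fitch")
  code <- bitwShiftL(1L, match(leaf_labels, alphabet) - 1L)
  res <- fitch_masks(topo, code)
  root_mask <- res$mask[topo$root]
  labels <- alphabet[bitwAnd(bitwShiftL(1L, seq_along(alphabet) - 1L),
                             root_mask) != 0L]
  list(labels = labels, cost = res$cost[topo$root])
}

# Core bitmask pass used by both the generic and the pair variant.
# leaf_mask: integer bitmask per tip (tip order), 0 = gap sentinel.
# When `gap_aware`, a child whose set is 0 is transparent: the parent
# inherits the other child's mask and cost; two 0 children give 0 / cost 0.
fitch_masks <- function(topo, leaf_mask, gap_aware = FALSE) {
  nn <- topo$ntip + topo$nnode
  mask <- integer(nn)
  cost <- integer(nn)
  mask[seq_len(topo$ntip)] <- leaf_mask
  kids <- topo$kids
  for (v in topo$internal) {
    l <- kids[1L, v]; r <- kids[2L, v]
    ml <- mask[l]; mr <- mask[r]
    if (gap_aware && (ml == 0L || mr == 0L)) {
      if (ml == 0L) { mask[v] <- mr; cost[v] <- cost[r] }
      else { mask[v] <- ml; cost[v] <- cost[l] }
      next
    }
    inter <- bitwAnd(ml, mr)
    if (inter != 0L) {
      mask[v] <- inter
      cost[v] <- cost[l] + cost[r]
    } else {
      mask[v] <- bitwOr(ml, mr)
      cost[v] <- cost[l] + cost[r] + 1L
    }
  }
  list(mask = mask, cost = cost)
}

#' Count covarying mutations for a column pair on the tree
#'
#' Gap-aware pair-label Fitch pass: each leaf is labelled with the
#' ordered base pair its sequence shows at columns `(i, j)`, or with the
#' gap sentinel when that pair is not one of the six canonical pairs
#' (any non-pairing observation, including gaps and ambiguity codes, is
#' replaced by the sentinel).  A sentinel child is transparent: its
#' parent inherits the other child's label set and cost, so non-pairing
#' sequences never influence the inferred mutations.  Two distinct
#' canonical pairs always count as one mutation event under ordinary
#' Fitch set logic (GC vs CG included).
#'
#' @param tree a rooted binary `ape::phylo` validated against `aln`
#'   ([validate_tree]); an unvalidated tree is accepted if its tip
#'   labels match the alignment names.
#' @param aln an [rna_alignment].
#' @param i,j column indices, `1 <= i < j <= L`.
#' @return a list with `m` (mutation count at the root) and `b` (number
#'   of leaves carrying a canonical pair).
#' @export
pair_fitch <- function(tree, aln, i, j) {
  stopifnot(inherits(aln, "rna_alignment"))
  L <- ncol(aln$mat)
  i <- as.integer(i); j <- as.integer(j)
  if (i >= j) stop("need i < j, got i = ", i, ", j = ", j)
  if (i < 1L || j > L) stop("column index out of range 1..", L)
  row_of_tip <- attr(tree, "row_of_tip")
  if (is.null(row_of_tip)) {
    tree <- validate_tree(tree, aln)
    row_of_tip <- attr(tree, "row_of_tip")
  }
  topo <- tree_topology(tree)
  codes <- pair_codes(aln$mat[row_of_tip, i], aln$mat[row_of_tip, j])
  leaf_mask <- integer(length(codes))
  leaf_mask[codes > 0L] <- bitwShiftL(1L, codes[codes > 0L] - 1L)
  res <- fitch_masks(topo, leaf_mask, gap_aware = TRUE)
  list(m = res$cost[topo$root], b = sum(codes > 0L))
}

# All-pairs (m, b) tables in one pass over column pairs; used by
# score_all_pairs.  Returns list of two L x L matrices (upper triangle).
pair_fitch_all <- function(tree, aln) {
  row_of_tip <- attr(tree, "row_of_tip")
  stopifnot(!is.null(row_of_tip))
  topo <- tree_topology(tree)
  L <- ncol(aln$mat)
  mat <- aln$mat[row_of_tip, , drop = FALSE]
  base_idx <- matrix(match(mat, c("A", "C", "G", "U")), nrow = nrow(mat))
  m_tab <- matrix(NA_integer_, L, L)
  b_tab <- matrix(NA_integer_, L, L)
  ntip <- topo$ntip
  kids <- topo$kids
  internal <- topo$internal
  root <- topo$root
  for (i in seq_len(L - 1L)) {
    xi <- base_idx[, i]
    for (j in (i + 1L):L) {
      yj <- base_idx[, j]
      codes <- integer(ntip)
      ok <- !is.na(xi) & !is.na(yj)
      if (any(ok)) codes[ok] <- .pair_code_table[cbind(xi[ok], yj[ok])]
      b <- sum(codes > 0L)
      b_tab[i, j] <- b
      if (b <= 1L) { m_tab[i, j] <- 0L; next }
      mask <- integer(ntip + topo$nnode)
      cost <- integer(ntip + topo$nnode)
      mask[seq_len(ntip)][codes > 0L] <-
        bitwShiftL(1L, codes[codes > 0L] - 1L)
      for (v in internal) {
        l <- kids[1L, v]; r <- kids[2L, v]
        ml <- mask[l]; mr <- mask[r]
        if (ml == 0L || mr == 0L) {
          if (ml == 0L) { mask[v] <- mr; cost[v] <- cost[r] }
          else { mask[v] <- ml; cost[v] <- cost[l] }
        } else {
          inter <- bitwAnd(ml, mr)
          if (inter != 0L) {
            mask[v] <- inter; cost[v] <- cost[l] + cost[r]
          } else {
            mask[v] <- bitwOr(ml, mr); cost[v] <- cost[l] + cost[r] + 1L
          }
        }
      }
      m_tab[i, j] <- cost[root]
    }
  }
  list(m = m_tab, b = b_tab)
}
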