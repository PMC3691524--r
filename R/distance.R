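#' Jukes-Cantor distance matrix with saturation convention
#'
#' Pairwise JC69 distances computed over columns where neither sequence
#' carries a gap or ambiguity code.  Distances that are undefined or
#' saturated -- p-distance above 0.75 (where the JC69 logarithm
#' diverges) or no comparable columns at all -- are set to `1000`, a
#' finite stand-in for infinity that downstream rooted-tree builders
#' accept.
#'
#' @param aln an [rna_alignment].
#' @return an object of class `dist_matrix`: a symmetric `N x N` numeric
#'   matrix with zero diagonal and `dimnames` equal to the sequence
#'   names.
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  m <- aln$mat
  n <- nrow(m)
  is_base <- matrix(m %in% c("A", "C", "G", "U"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (k in seq_len(n - 1L)) {
    for (l in (k + 1L):n) {
      keep <- is_base[k, ] & is_base[l, ]
      nn <- sum(keep)
      if (nn == 0L) { d[k, l] <- d[l, k] <- 1000; next }
      p <- sum(m[k, keep] != m[l, keep]) / nn
      d[k, l] <- d[l, k] <-
        if (p > 0.75) 1000 else -0.75 * log(1 - 4 * p / 3)
    }
  }
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm a `dist_matrix` (or any named symmetric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  dm <- unclass(dm)
  n <- nrow(dm)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(k) {
               paste0(sprintf("%-10s", rownames(dm)[k]),
                      paste(sprintf("%10.6f", dm[k, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering producing a rooted, binary,
#' ultrametric tree.  Joins are deterministic: at equal heights the
#' candidate involving the lowest row index is merged first (the
#' behaviour of [stats::hclust]).  This builder is a convenience so the
#' pipeline runs without external phylogeny programs; any rooted binary
#' tree from any source can be used instead.
#'
#' @param dm a `dist_matrix` from [distance_matrix] (or compatible named
#'   symmetric matrix).
#' @return a rooted binary ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(dm) {
  dm <- unclass(dm)
  if (nrow(dm) < 2L) stop("need at least 2 taxa to build a tree")
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}
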