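#' Configuration for the synthetic alignment generator
#'
#' The generator evolves a root sequence down a rooted binary tree under
#' a *coupled-switch* model: at columns paired in the true consensus
#' structure, a substitution replaces the whole canonical base pair with
#' a different canonical pair at both partners simultaneously (so the
#' structure is preserved and the number of covarying mutations is
#' directly controlled); at unpaired columns, bases substitute
#' independently.  Gaps are introduced at leaves, at unpaired columns
#' only.  Branch lengths are ignored: rates are per branch.
#'
#' @param tree a rooted binary `ape::phylo`, or an integer taxon count
#'   (a random topology is drawn).
#' @param structure an [rna_structure] or dot-bracket string: the true
#'   consensus structure (its length sets the sequence length).
#' @param sub_rate per-branch substitution probability at unpaired
#'   columns (default 0.15).
#' @param switch_rate per-branch probability of a covarying pair switch
#'   at each paired column pair (default 0.30).
#' @param gap_prob per-leaf, per-unpaired-column gap probability
#'   (default 0.05).
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree, structure, sub_rate = 0.15,
                       switch_rate = 0.30, gap_prob = 0.05, seed = 1L) {
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  stopifnot(inherits(structure, "rna_structure"))
  for (r in c(sub_rate, switch_rate, gap_prob))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  structure(list(tree = tree, structure = structure,
                 sub_rate = sub_rate, switch_rate = switch_rate,
                 gap_prob = gap_prob, seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate an alignment with a known tree and consensus structure
#'
#' @param cfg a [sim_config].
#' @return a list with `aln` (an [rna_alignment]), `tree` (the
#'   generating rooted binary `ape::phylo`), and `structure` (the true
#'   consensus [rna_structure]).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    tree <- cfg$tree
    if (is.numeric(tree)) tree <- ape::rtree(as.integer(tree))
    tree <- check_binary_rooted(tree)
    st <- cfg$structure
    L <- st$length
    pairs <- st$pairs
    paired_cols <- c(pairs)
    unpaired_cols <- setdiff(seq_len(L), paired_cols)
    bases <- c("A", "C", "G", "U")
    # root sequence
    root <- character(L)
    root[unpaired_cols] <- sample(bases, length(unpaired_cols),
                                  replace = TRUE)
    if (nrow(pairs)) {
      pr <- sample(CANONICAL_PAIRS, nrow(pairs), replace = TRUE)
      for (k in seq_len(nrow(pairs))) {
        bp <- strsplit(pr[k], "")[[1L]]
        root[pairs[k, 1]] <- bp[1L]
        root[pairs[k, 2]] <- bp[2L]
      }
    }
    topo <- tree_topology(tree)
    nn <- topo$ntip + topo$nnode
    seqs <- vector("list", nn)
    seqs[[topo$root]] <- root
    # preorder: parents before children
    po <- ape::reorder.phylo(tree, "postorder")
    edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; child <- edges[e, 2]
      s <- seqs[[par]]
      if (length(unpaired_cols)) {
        mut <- unpaired_cols[stats::runif(length(unpaired_cols)) <
                               cfg$sub_rate]
        for (cix in mut)
          s[cix] <- sample(setdiff(bases, s[cix]), 1L)
      }
      if (nrow(pairs)) {
        sw <- which(stats::runif(nrow(pairs)) < cfg$switch_rate)
        for (k in sw) {
          cur <- paste0(s[pairs[k, 1]], s[pairs[k, 2]])
          new <- sample(setdiff(CANONICAL_PAIRS, cur), 1L)
          bp <- strsplit(new, "")[[1L]]
          s[pairs[k, 1]] <- bp[1L]
          s[pairs[k, 2]] <- bp[2L]
        }
      }
      seqs[[child]] <- s
    }
    rows <- vapply(seq_len(topo$ntip), function(t) {
      s <- seqs[[t]]
      if (cfg$gap_prob > 0 && length(unpaired_cols)) {
        g <- unpaired_cols[stats::runif(length(unpaired_cols)) <
                             cfg$gap_prob]
        s[g] <- "-"
      }
      paste(s, collapse = "")
    }, "")
    aln <- rna_alignment(rows, names = tree$tip.label,
                         metadata = list(SS_cons = serialize_dotbracket(st)))
    list(aln = aln, tree = tree, structure = st)
  })
}

#' Randomly subsample alignment rows
#'
#' @param aln an [rna_alignment].
#' @param k number of rows to keep, `2 <= k <= N`.
#' @param seed integer seed.
#' @param drop_allgap drop columns that become all-gap after
#'   subsampling.
#' @return an [rna_alignment] with `k` rows, in original row order.
#' @export
subsample_alignment <- function(aln, k, seed = 1L, drop_allgap = FALSE) {
  stopifnot(inherits(aln, "rna_alignment"))
  N <- nrow(aln$mat)
  k <- as.integer(k)
  if (k < 2L || k > N) stop("k must be in 2..", N)
  keep <- if (k == N) seq_len(N) else
    with_seed(seed, sort(sample.int(N, k)))
  m <- aln$mat[keep, , drop = FALSE]
  if (drop_allgap) {
    good <- colSums(m != "-") > 0L
    m <- m[, good, drop = FALSE]
  }
  rna_alignment(apply(m, 1L, paste, collapse = ""),
                names = aln$names[keep], metadata = aln$metadata)
}
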