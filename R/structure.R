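#' Construct a secondary structure object
#'
#' A set of base pairs on `L` positions.  Pairs are 1-based `(i, j)` with
#' `i < j`; no position may occur in more than one pair and pairs must be
#' non-crossing (for `(i, j)` and `(k, l)` with `i < k`: either `j < k`
#' or `l < j`), i.e. the structure is a pseudoknot-free nesting.
#'
#' @param length number of positions `L`.
#' @param pairs two-column integer matrix of base pairs (may have zero
#'   rows); a `list` of length-2 vectors is also accepted.
#' @return an object of class `rna_structure` with fields `length` and
#'   `pairs` (matrix sorted by `i`).
#' @export
rna_structure <- function(length, pairs = matrix(integer(0), 0, 2)) {
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  if (is.null(pairs) || !length(pairs)) pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  length <- as.integer(length)
  if (length < 1L) stop("structure length must be >= 1")
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1] < 1L) || any(pairs[, 2] > length))
      stop("pair index out of range 1..", length)
    if (any(pairs[, 1] == pairs[, 2]))
      stop("a position cannot pair with itself")
    idx <- c(pairs)
    if (anyDuplicated(idx))
      stop("position(s) ", paste(unique(idx[duplicated(idx)]),
                                 collapse = ", "),
           " occur in more than one pair")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    if (pairs_cross(pairs))
      stop("crossing base pairs (pseudoknot) are not allowed")
  }
  colnames(pairs) <- c("i", "j")
  structure(list(length = length, pairs = pairs), class = "rna_structure")
}

# TRUE if any two pairs cross; `pairs` sorted by i
pairs_cross <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (k < j && j < l) return(TRUE)
    }
  }
  FALSE
}

#' Parse a dot-bracket / WUSS string
#'
#' Round brackets `()` as well as the WUSS glyphs `<>`, `[]`, `{}` and
#' matched upper/lower-case letter pairs (`Aa`, `Bb`, ...) are accepted
#' as pairs; the WUSS unpaired glyphs `: , _ - ~ .` all map to unpaired.
#' Matching is stack-based per bracket family.
#'
#' @param s the structure string.
#' @return an [rna_structure].
#' @export
parse_dotbracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ch <- strsplit(s, "")[[1L]]
  L <- length(ch)
  if (L == 0L) stop("empty structure string")
  openers <- c("(" = ")", "<" = ">", "[" = "]", "{" = "}",
               stats::setNames(letters, LETTERS))
  unpaired <- c(".", ":", ",", "_", "-", "~")
  stacks <- list()
  pairs <- list()
  for (pos in seq_len(L)) {
    c0 <- ch[pos]
    if (c0 %in% unpaired) next
    if (c0 %in% names(openers)) {
      key <- openers[[c0]]
      stacks[[key]] <- c(stacks[[key]], pos)
    } else if (c0 %in% unname(openers)) {
      st <- stacks[[c0]]
      if (!length(st))
        stop("unbalanced structure string: unmatched '", c0,
             "' at position ", pos)
      pairs[[length(pairs) + 1L]] <- c(st[length(st)], pos)
      stacks[[c0]] <- st[-length(st)]
    } else {
      stop("invalid structure character '", c0, "' at position ", pos)
    }
  }
  left <- vapply(stacks, length, 1L)
  if (any(left > 0L)) {
    key <- names(stacks)[which(left > 0L)[1L]]
    pos <- stacks[[key]][1L]
    stop("unbalanced structure string: unmatched opener at position ", pos)
  }
  rna_structure(L, pairs)
}

#' Serialize a structure to dot-bracket
#'
#' Nested pairs are emitted as `(` / `)`; unpaired positions as `.`.
#'
#' @param x an [rna_structure].
#' @return a dot-bracket string of length `x$length`.
#' @export
serialize_dotbracket <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  out <- rep(".", x$length)
  if (nrow(x$pairs)) {
    out[x$pairs[, 1]] <- "("
    out[x$pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

#' @export
as.character.rna_structure <- function(x, ...) serialize_dotbracket(x)

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: L = ", x$length, ", ",
      nrow(x$pairs), " base pairs\n  ", serialize_dotbracket(x), "\n",
      sep = "")
  invisible(x)
}

#' @export
`==.rna_structure` <- function(e1, e2) {
  e1$length == e2$length && nrow(e1$pairs) == nrow(e2$pairs) &&
    all(e1$pairs == e2$pairs)
}
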