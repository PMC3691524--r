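#' Simplified nearest-neighbour energy model
#'
#' A pluggable loop-energy parameter set for consensus folding.  It is a
#' deliberately small model -- a 6 x 6 stacking table over the canonical
#' pairs, logarithmic length penalties for hairpin and interior loops,
#' and an affine multiloop score -- with Turner-like magnitudes
#' (kcal/mol).  Folding correctness in this package is established
#' against a brute-force oracle under the *same* model, so any table
#' dropped in via [read_energy_model] is treated consistently.
#'
#' Per-sequence evaluation: a sequence contributes loop energy for a
#' loop only when its own bases at the closing columns form a canonical
#' pair (the mispairing cost of other sequences is already carried by
#' the penalty score `Q` inside the covariance term); loop sizes are
#' measured in that sequence's gap-stripped coordinates.
#'
#' @param stack 6 x 6 matrix of stacking energies indexed by the outer
#'   and inner canonical pair (order `AU, UA, CG, GC, GU, UG`).
#' @param hairpin_a,hairpin_b hairpin initiation: `hairpin_a +
#'   hairpin_b * log(n / 3)` for an `n >= 3` nt loop.
#' @param hairpin_short finite penalty for a (gap-induced) hairpin loop
#'   shorter than 3 nt in a particular sequence.
#' @param interior_a,interior_b interior/bulge initiation: `interior_a +
#'   interior_b * log(n)` for `n >= 1` total unpaired nt.
#' @param Ma,Mb,Mc multiloop closing penalty, per-branch penalty, and
#'   per-unpaired-column penalty (applied once per sequence).
#' @param max_interior maximum total unpaired span of an interior loop,
#'   in alignment columns; larger interior loops are disallowed.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(stack = default_stack_table(),
                         hairpin_a = 5.6, hairpin_b = 1.7,
                         hairpin_short = 6.0,
                         interior_a = 1.1, interior_b = 1.1,
                         Ma = 3.4, Mb = 0.4, Mc = 0.1,
                         max_interior = 30L) {
  stopifnot(is.matrix(stack), all(dim(stack) == 6L),
            all(is.finite(stack)))
  dimnames(stack) <- list(CANONICAL_PAIRS, CANONICAL_PAIRS)
  structure(list(stack = stack, hairpin_a = hairpin_a,
                 hairpin_b = hairpin_b, hairpin_short = hairpin_short,
                 interior_a = interior_a, interior_b = interior_b,
                 Ma = Ma, Mb = Mb, Mc = Mc,
                 max_interior = as.integer(max_interior)),
            class = "energy_model")
}

#' Default stacking energy table
#'
#' Turner-like stacking free energies (kcal/mol) for the canonical
#' pairs, outer pair in rows, inner pair in columns (both read 5'-3' on
#' the same strand side).
#'
#' @return a 6 x 6 numeric matrix.
#' @export
default_stack_table <- function() {
  # order: AU UA CG GC GU UG
  m <- matrix(c(
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,
    -1.3, -1.4, -2.5, -2.1, -0.5, 1.3,
    -1.0, -0.6, -1.5, -1.4, 0.3, -0.5), 6, 6, byrow = TRUE)
  dimnames(m) <- list(CANONICAL_PAIRS, CANONICAL_PAIRS)
  m
}

#' Read an energy model from a key-value text file
#'
#' Format: `key value` lines for the scalar parameters
#' (`hairpin_a hairpin_b hairpin_short interior_a interior_b Ma Mb Mc
#' max_interior`) and a `stack` block of 6 lines of 6 numbers (rows and
#' columns in canonical-pair order `AU UA CG GC GU UG`); `#` starts a
#' comment.
#'
#' @param path file path.
#' @return an [energy_model].
#' @export
read_energy_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  stack <- NULL
  k <- 1L
  while (k <= length(lines)) {
    parts <- strsplit(lines[k], "[ \t]+")[[1L]]
    if (identical(parts[1L], "stack")) {
      block <- lines[(k + 1L):(k + 6L)]
      stack <- do.call(rbind, lapply(strsplit(block, "[ \t]+"),
                                     as.numeric))
      k <- k + 7L
    } else {
      kv[[parts[1L]]] <- as.numeric(parts[2L])
      k <- k + 1L
    }
  }
  args <- kv
  if (!is.null(stack)) args$stack <- stack
  do.call(energy_model, args)
}

#' Write an energy model to the key-value text format
#'
#' @param em an [energy_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_model <- function(em, path) {
  sc <- c("hairpin_a", "hairpin_b", "hairpin_short", "interior_a",
          "interior_b", "Ma", "Mb", "Mc", "max_interior")
  lines <- c("# simplified nearest-neighbour energy model (kcal/mol)",
             sprintf("%s %g", sc, vapply(sc, function(k) em[[k]], 0)),
             "# stacking: rows outer pair, cols inner pair; order AU UA CG GC GU UG",
             "stack",
             apply(em$stack, 1L, function(r)
               paste(sprintf("%g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

# hairpin loop energy for one sequence with n unpaired (degapped) nt
hairpin_len_energy <- function(em, n) {
  if (n < 3) em$hairpin_short
  else em$hairpin_a + em$hairpin_b * log(n / 3)
}

# interior/bulge initiation for total unpaired length n >= 1
interior_len_energy <- function(em, n) {
  em$interior_a + em$interior_b * log(n)
}
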