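#' Construct an RNA alignment object
#'
#' An `rna_alignment` holds `N >= 2` aligned RNA sequences of identical
#' length `L` over the alphabet `A, C, G, U, -` (plus IUPAC ambiguity
#' codes, which are retained but treated as non-pairing by every scoring
#' rule).  On construction sequences are normalized: upper-cased, `T`
#' mapped to `U`, and every gap glyph (`-`, `.`, `~`) mapped to `-`.
#'
#' @param seqs character vector of aligned sequences.
#' @param names unique sequence identifiers; defaults to `names(seqs)` or
#'   `seq1 ... seqN`.
#' @param metadata optional named list of free-form tags (e.g. the
#'   `SS_cons` line of a Stockholm file).
#' @return an object of class `rna_alignment` with fields `names`, `seqs`
#'   (normalized strings), `mat` (N x L character matrix), `metadata`.
#' @export
rna_alignment <- function(seqs, names = NULL, metadata = list()) {
  if (is.null(names)) names <- base::names(seqs)
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  seqs <- as.character(seqs)
  names <- as.character(names)
  if (length(seqs) < 2L)
    stop("an alignment needs at least 2 sequences, got ", length(seqs))
  if (length(names) != length(seqs))
    stop("length of 'names' does not match number of sequences")
  if (anyDuplicated(names))
    stop("duplicated sequence names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names[lens != lens[1L]][1L]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[names == bad][1L]), ", expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment has zero columns")
  seqs <- normalize_rna(seqs)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]),
                 strsplit("ACGU-RYSWKMBDHVN", "")[[1L]])
  if (length(bad))
    stop("unknown characters in alignment: ", paste(bad, collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names
  structure(list(names = names, seqs = stats::setNames(seqs, names),
                 mat = mat, metadata = metadata),
            class = "rna_alignment")
}

normalize_rna <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  x <- gsub("[.~]", "-", x)
  x
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("RNA alignment: ", nrow(x$mat), " sequences, ", ncol(x$mat),
      " columns\n", sep = "")
  show <- utils::head(x$names, 6L)
  for (nm in show) {
    s <- x$seqs[[nm]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", nm, s))
  }
  if (length(x$names) > 6L) cat("  ... and ", length(x$names) - 6L,
                                " more\n", sep = "")
  if (!is.null(x$metadata$SS_cons))
    cat("  SS_cons: ", x$metadata$SS_cons, "\n", sep = "")
  invisible(x)
}

#' @export
dim.rna_alignment <- function(x) dim(x$mat)

#' Read a multiple RNA alignment
#'
#' Supported formats: aligned FASTA (via Biostrings), CLUSTAL, and
#' Stockholm 1.0.  A Stockholm `#=GC SS_cons` annotation line, when
#' present, is preserved verbatim in `metadata$SS_cons`.
#'
#' @param path path to the alignment file.
#' @param format one of `"stockholm"`, `"clustal"`, `"fasta"`, or
#'   `"auto"` (sniff from the first line).
#' @return an [rna_alignment].
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "clustal",
                                            "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm"
    else if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
    else if (grepl("^>", first)) "fasta"
    else stop("cannot auto-detect alignment format of ", path)
  }
  switch(format,
         fasta = read_fasta_alignment(path),
         clustal = read_clustal_alignment(path),
         stockholm = read_stockholm_alignment(path))
}

read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rna_alignment(as.character(set), names = names(set))
}

read_clustal_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("not a CLUSTAL file (missing header): ", path)
  lines <- lines[-1L]
  seqs <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only  * : . and spaces
    if (grepl("^[ \t]", ln) || grepl("^[*:. ]+$", ln)) next
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) < 2L) next
    nm <- parts[1L]
    chunk <- gsub("[0-9]", "", paste(parts[-1L], collapse = ""))
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "", chunk)
  }
  if (!length(seqs)) stop("no sequences found in CLUSTAL file: ", path)
  rna_alignment(seqs)
}

read_stockholm_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  seqs <- character(0)
  gc <- character(0)
  for (ln in lines[-1L]) {
    if (grepl("^//", ln) ) break
    if (!nzchar(trimws(ln))) next
    if (grepl("^#=GC[ \t]", ln)) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(parts) >= 3L) {
        tag <- parts[2L]
        gc[tag] <- paste0(if (tag %in% names(gc)) gc[[tag]] else "",
                          paste(parts[-(1:2)], collapse = ""))
      }
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    nm <- parts[1L]
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "",
                       parts[2L])
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file: ", path)
  md <- as.list(gc)
  rna_alignment(seqs, metadata = md)
}

#' Write a multiple RNA alignment
#'
#' @param aln an [rna_alignment].
#' @param path output file path.
#' @param format `"stockholm"`, `"clustal"`, or `"fasta"`.
#' @param ss_cons optional dot-bracket/WUSS string written as
#'   `#=GC SS_cons` (Stockholm only); defaults to `metadata$SS_cons`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path,
                            format = c("stockholm", "clustal", "fasta"),
                            ss_cons = NULL) {
  stopifnot(inherits(aln, "rna_alignment"))
  format <- match.arg(format)
  if (is.null(ss_cons)) ss_cons <- aln$metadata$SS_cons
  if (format == "fasta") {
    set <- Biostrings::BStringSet(aln$seqs)
    Biostrings::writeXStringSet(set, path)
    return(invisible(path))
  }
  w <- max(nchar(aln$names), 12L)
  if (format == "clustal") {
    out <- c("CLUSTAL W multiple sequence alignment", "",
             sprintf("%-*s %s", w, aln$names, aln$seqs))
  } else {
    out <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, aln$names, aln$seqs))
    if (!is.null(ss_cons))
      out <- c(out, sprintf("%-*s %s", w, "#=GC SS_cons", ss_cons))
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Mean pairwise identity of an alignment
#'
#' Mean over all sequence pairs of the fraction of identical aligned
#' positions among positions where not both sequences carry a gap,
#' expressed as a percentage.
#'
#' @param aln an [rna_alignment].
#' @return a percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  m <- aln$mat
  n <- nrow(m)
  tot <- 0
  cnt <- 0L
  for (k in seq_len(n - 1L)) {
    for (l in (k + 1L):n) {
      keep <- !(m[k, ] == "-" & m[l, ] == "-")
      denom <- sum(keep)
      ident <- if (denom == 0L) 1 else
        sum(m[k, keep] == m[l, keep] & m[k, keep] != "-") / denom
      tot <- tot + ident
      cnt <- cnt + 1L
    }
  }
  100 * tot / cnt
}
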