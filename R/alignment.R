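ALPHABET <- c("A", "C", "G", "T", "-")
GAP <- "-"

#' Construct an aligned sequence matrix
#'
#' An alignment is a character matrix over the 5-symbol alphabet
#' `{A, C, G, T, -}` with one row per taxon (rownames are the taxon labels)
#' and one column per site. The gap symbol is `-` only; ambiguity codes such
#' as `N` or `?` are rejected, because the analyses in this package concern
#' indel gaps specifically, not uncertain base calls.
#'
#' @param x either a character matrix (rows = taxa), or a named character
#'   vector of equal-length aligned sequences.
#' @return a validated character matrix of class `gapml_alignment`.
#' @examples
#' aln <- alignment(c(s1 = "A--", s2 = "-C-", s3 = "A--"))
#' @export
alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) > 1)
      stop("aligned sequences must all have the same length")
    mat <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(mat) <- names(x)
  } else if (is.matrix(x)) {
    mat <- toupper(x)
    if (is.null(rownames(mat))) stop("alignment matrix must have rownames")
  } else {
    stop("cannot build an alignment from an object of class ",
         paste(class(x), collapse = "/"))
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate taxon labels")
  bad <- setdiff(unique(as.vector(mat)), ALPHABET)
  if (length(bad))
    stop("alignment contains characters outside {A,C,G,T,-}: ",
         paste(bad, collapse = ", "),
         " (ambiguity codes such as 'N' or '?' are not treated as gaps)")
  structure(mat, class = c("gapml_alignment", "matrix", "array"))
}

#' Number of sites in an alignment
#' @param aln an alignment.
#' @return integer site count R.
#' @export
n_sites <- function(aln) ncol(aln)

#' @export
print.gapml_alignment <- function(x, ...) {
  cat(nrow(x), "taxa x", ncol(x), "sites\n")
  seqs <- apply(unclass(x), 1, paste, collapse = "")
  for (i in seq_along(seqs))
    cat(format(rownames(x)[i], width = max(nchar(rownames(x))) + 2), seqs[i], "\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased on read and validated against the
#' `{A, C, G, T, -}` alphabet.
#'
#' @param path path to an aligned FASTA file.
#' @return a `gapml_alignment`.
#' @export
read_alignment <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  alignment(toupper(d))
}

#' Write an alignment to aligned FASTA
#'
#' @param aln a `gapml_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove every site containing a gap
#'
#' The classical "strip gapped columns" treatment: only columns with zero
#' gaps are retained, in their original order. On heavily gapped input this
#' can return an alignment with zero sites.
#'
#' @param aln a `gapml_alignment`.
#' @return a `gapml_alignment` with the gap-free columns only.
#' @export
strip_gapped_sites <- function(aln) {
  keep <- colSums(unclass(aln) == GAP) == 0
  structure(unclass(aln)[, keep, drop = FALSE],
            class = c("gapml_alignment", "matrix", "array"))
}

#' Is an alignment monotypic?
#'
#' An alignment is monotypic when every column shows exactly one nucleotide
#' type among its non-gap entries (all A, all C, all G or all T) and no
#' column is entirely gapped.
#'
#' @param aln a `gapml_alignment`.
#' @return logical.
#' @export
is_monotypic <- function(aln) {
  if (ncol(aln) == 0L) return(TRUE)
  all(apply(unclass(aln), 2, function(col) {
    nuc <- unique(col[col != GAP])
    length(nuc) == 1L
  }))
}

#' Code gapped columns as binary presence/absence characters
#'
#' Every column containing at least one gap yields one binary character:
#' 1 where the taxon carries a nucleotide at that site, 0 where it carries a
#' gap. Columns without gaps are not coded. The original (0-based) site index
#' of each character is recorded as provenance.
#'
#' @param aln a `gapml_alignment`.
#' @return an object of class `gap_characters`: a list with `taxa`, the
#'   binary `matrix` (taxa x K), and `sites` (0-based source column indices).
#' @export
gap_code <- function(aln) {
  gapped <- which(colSums(unclass(aln) == GAP) > 0)
  mat <- matrix(as.integer(unclass(aln)[, gapped, drop = FALSE] != GAP),
                nrow = nrow(aln),
                dimnames = list(rownames(aln), NULL))
  structure(list(taxa = rownames(aln), matrix = mat,
                 sites = as.integer(gapped - 1L)),
            class = "gap_characters")
}

#' @export
print.gap_characters <- function(x, ...) {
  cat("gap characters:", ncol(x$matrix), "binary characters on",
      length(x$taxa), "taxa\n")
  if (ncol(x$matrix))
    cat("source sites (0-based):", paste(x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Write gap characters as a relaxed PHYLIP-style 0/1 matrix
#'
#' The first line is a comment recording the 0-based source sites, then a
#' `ntaxa nchar` header, then one `label  01...` row per taxon.
#'
#' @param gc a `gap_characters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gap_characters <- function(gc, path) {
  header <- paste0("# source sites (0-based): ",
                   paste(gc$sites, collapse = ","))
  dims <- paste(length(gc$taxa), ncol(gc$matrix))
  rows <- paste(format(gc$taxa, width = max(nchar(gc$taxa)) + 2),
                apply(gc$matrix, 1, paste, collapse = ""))
  writeLines(c(header, dims, rows), path)
  invisible(path)
}
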