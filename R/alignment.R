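#' Multiple sequence alignment container
#'
#' A light container for aligned sequences: a named character vector of
#' equal-length strings over IUPAC DNA symbols plus `-` for gaps. Case is
#' normalised to upper case; symbols are preserved otherwise.
#'
#' @param seqs named character vector (or named list) of aligned sequences.
#' @return an object of class `alignment` with fields `ids`, `rows`
#'   (character matrix, one row per sequence) and `length`.
#' @export
alignment <- function(seqs) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("sequences must carry unique names")
  if (length(seqs) < 2L) stopf("an alignment needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stopf("aligned sequences must all have the same length")
  rows <- do.call(rbind, lapply(seqs, function(s) to_residues(s)))
  rownames(rows) <- names(seqs)
  structure(list(ids = names(seqs), rows = rows, length = unname(lens[1])),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

# One sequence of an alignment as a residue vector.
aln_row <- function(aln, id) {
  if (!id %in% aln$ids) stopf("unknown sequence id '%s'", id)
  aln$rows[id, ]
}

# Alignment rows as single strings.
aln_strings <- function(aln) {
  setNames(apply(aln$rows, 1, paste, collapse = ""), aln$ids)
}

#' Read an alignment from a FASTA file
#'
#' Thin wrapper over [ape::read.FASTA()]; gaps (`-`) and IUPAC symbols are
#' preserved, case is normalised.
#'
#' @param path FASTA file.
#' @return an [alignment()].
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  alignment(seqs)
}

#' Write an alignment (or named sequences) to FASTA
#'
#' @param x an [alignment()] or named character vector of sequences.
#' @param path output file.
#' @export
write_fasta_alignment <- function(x, path) {
  seqs <- if (inherits(x, "alignment")) aln_strings(x) else unlist(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Remove a set of columns from an alignment
#'
#' Used to excise ambiguously aligned regions before indel coding and
#' parsimony; the mask is an explicit, audited column set rather than an
#' automatic heuristic.
#'
#' @param aln an [alignment()].
#' @param columns integer columns to drop (1-based).
#' @return a masked [alignment()].
#' @export
mask_columns <- function(aln, columns) {
  stopifnot(inherits(aln, "alignment"))
  columns <- unique(as.integer(columns))
  if (!length(columns)) return(aln)
  if (any(columns < 1L | columns > aln$length))
    stopf("mask columns outside alignment bounds")
  keep <- setdiff(seq_len(aln$length), columns)
  alignment(apply(aln$rows[, keep, drop = FALSE], 1, paste, collapse = ""))
}
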