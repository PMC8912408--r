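# The multiple-sequence-alignment container and FASTA I/O.

#' Construct a DNA alignment
#'
#' Stored as a character matrix (rows = taxa, columns = alignment sites) over
#' A/C/G/T/N, '-', and IUPAC ambiguity letters.
#'
#' @param sequences Named character vector of equal-length aligned sequences,
#'   or a character matrix of single characters with rownames.
#' @return Object of class `dna_alignment` (a character matrix).
#' @export
dna_alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences)) || any(names(sequences) == ""))
      ps_abort("alignment sequences must be named by taxon", "ps_validation_error")
    w <- nchar(sequences)
    if (length(unique(w)) > 1L)
      ps_abort(sprintf("ragged alignment: row lengths %s",
                       paste(unique(w), collapse = ", ")),
               "ps_ragged_alignment_error")
    m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (anyDuplicated(rownames(m)))
    ps_abort("duplicate taxon ids in alignment", "ps_validation_error")
  class(m) <- c("dna_alignment", class(m))
  m
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d taxa x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`; ambiguity
#'   codes retained).
#' @return A [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    ps_abort(paste0(path, ": empty FASTA"), "ps_validation_error")
  seqs <- stats::setNames(toupper(as.character(set)),
                          sub("\\s.*$", "", names(set)))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L)
    ps_abort(sprintf("%s: ragged alignment (row lengths %s)", path,
                     paste(sort(unique(w)), collapse = ", ")),
             "ps_ragged_alignment_error")
  if (anyDuplicated(names(seqs)))
    ps_abort(paste0(path, ": duplicate taxon ids"), "ps_validation_error")
  dna_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln A [dna_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
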