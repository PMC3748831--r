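#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings giving named character vectors, the
#' representation the rest of the package uses for reference and transcript
#' sequences. Names are truncated at the first whitespace (the sequence
#' accession).
#'
#' @param path path to a FASTA file.
#' @return `read_fasta()`: a named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param x named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Transcript lengths from sequences
#'
#' @param x named character vector of sequences (or a `DNAStringSet`).
#' @return named integer vector of sequence lengths in bases.
#' @export
transcript_lengths <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- Biostrings::width(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  stats::setNames(nchar(x), names(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
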