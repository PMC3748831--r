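#' Canonical k-mer contaminant index
#'
#' An alignment-free replacement for aligning reads to an rRNA/mtRNA catalog:
#' the index stores the canonical form (lexicographic minimum of a k-mer and
#' its reverse complement) of every length-`k` window of the reference
#' sequences, making membership strand-agnostic. Windows containing `N` are
#' skipped.
#'
#' @param references reference sequences: a named character vector, a
#'   [read_set], or a `DNAStringSet`.
#' @param k k-mer length (default 25).
#' @return `build_kmer_index()`: a `kmer_index` object with fields `k` and
#'   `kmers` (character vector of canonical k-mers).
#' @examples
#' idx <- build_kmer_index(c(ref = "ACGTA"), k = 4)
#' sort(idx$kmers)
#' @export
build_kmer_index <- function(references, k = 25) {
  seqs <- as_sequences(references)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (length(seqs) == 0L || all(nchar(seqs) < k)) {
    if (length(seqs))
      warning(sprintf("k = %d exceeds every reference length; empty index", k))
    return(structure(list(k = k, kmers = character()), class = "kmer_index"))
  }
  structure(list(k = k, kmers = cpp_canonical_kmers(toupper(seqs), k)),
            class = "kmer_index")
}

as_sequences <- function(x) {
  if (inherits(x, "read_set")) return(x$sequence)
  if (is(x, "DNAStringSet")) return(as.character(x))
  as.character(x)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d canonical %d-mer(s)\n", length(x$kmers), x$k))
  invisible(x)
}

#' Screen reads against a contaminant k-mer index
#'
#' A read is flagged as contaminant when at least `min_shared` of its k-mer
#' windows have a canonical form present in the index. Reads copied verbatim
#' from an indexed reference (length >= k) always share all their k-mers and
#' are therefore always flagged.
#'
#' @param reads a [read_set] (or character vector of sequences).
#' @param index a `kmer_index` from [build_kmer_index()].
#' @param min_shared minimum number of shared canonical k-mers (default 1).
#' @return logical vector, `TRUE` for contaminant reads.
#' @export
filter_contaminant <- function(reads, index, min_shared = 1) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- as_sequences(reads)
  cpp_shared_kmer_counts(seqs, index$kmers, index$k) >= min_shared
}

#' @rdname filter_contaminant
#' @return `shared_kmer_count()`: integer vector of shared canonical k-mer
#'   window counts per read.
#' @export
shared_kmer_count <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_shared_kmer_counts(as_sequences(reads), index$kmers, index$k)
}
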