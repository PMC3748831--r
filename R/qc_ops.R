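#' Clip adapter read-through from the 3' end of reads
#'
#' Scans each read left to right for the leftmost position where a prefix of
#' the adapter matches the read suffix with overlap at least `min_overlap`
#' and a mismatch fraction at most `max_mismatch_rate`; a full internal
#' adapter occurrence (not only a suffix overlap) also qualifies. The
#' sequence and qualities are truncated at that position; reads with no
#' qualifying match are unchanged. `N` never matches.
#'
#' @param reads a [read_set].
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum read/adapter overlap in bases (default 5).
#' @param max_mismatch_rate maximum mismatch fraction over the overlap
#'   (default 0.1).
#' @return the clipped [read_set].
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 5,
                         max_mismatch_rate = 0.1) {
  adapter <- toupper(as.character(adapter))
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  stopifnot(min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 1)
  keep <- cpp_clip_lengths(reads$sequence, adapter, as.integer(min_overlap),
                           max_mismatch_rate)
  truncate_reads(reads, keep)
}

truncate_reads <- function(reads, keep) {
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  reads
}

#' Flag low-complexity reads
#'
#' A read is low complexity when its sequence contains at most two distinct
#' bases among `A`,`C`,`G`,`T` — a signature of technical artifacts. `N` is
#' ignored, so an all-`N` (or empty) read is low complexity.
#'
#' @param reads a [read_set].
#' @return logical vector, `TRUE` for low-complexity reads.
#' @export
is_low_complexity <- function(reads) {
  cpp_unique_base_count(as_sequences(reads)) <= 2L
}

#' Trim a fixed-length prefix from reads
#'
#' Removes the first `n` bases (sequence and qualities) of every read,
#' saturating at the read length. Used to remove the positional GC bias of
#' random-hexamer priming at the read start.
#'
#' @param reads a [read_set].
#' @param n number of leading bases to remove (default 13).
#' @return the trimmed [read_set].
#' @export
trim_prefix <- function(reads, n = 13) {
  stopifnot(n >= 0)
  reads$sequence <- substring(reads$sequence, n + 1L)
  reads$quality <- substring(reads$quality, n + 1L)
  reads
}

#' Adaptive 3' quality trimming
#'
#' Slides a window of `window` bases from the end of the read toward the
#' start, removing the final base and shifting the window by one while the
#' window's mean quality is below `min_mean_quality`, until the mean reaches
#' the threshold. When fewer than `window` bases remain, the mean test is
#' applied once to all remaining bases (removing them all if it fails). The
#' result is always a prefix of the input and the operation is idempotent.
#'
#' @param reads a [read_set].
#' @param window window width in bases (default 5).
#' @param min_mean_quality minimum mean Phred quality (default 30).
#' @return the trimmed [read_set].
#' @examples
#' r <- seq_record("r", strrep("A", 10), c(rep(40, 5), rep(2, 5)))
#' nchar(adaptive_trim_3prime(r)$sequence)  # 6
#' @export
adaptive_trim_3prime <- function(reads, window = 5, min_mean_quality = 30) {
  stopifnot(window >= 1)
  keep <- cpp_trim_lengths(reads$quality, as.integer(window), min_mean_quality)
  truncate_reads(reads, keep)
}
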