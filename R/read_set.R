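#' Sequence read sets
#'
#' A `read_set` is the unit that flows through quality control: a data frame
#' with one row per read and columns `read_id`, `mate` (1, 2, or 0 for
#' unpaired), `sequence` (over `A`,`C`,`G`,`T`,`N`) and `quality` (per-base
#' Phred scores, stored internally as a Phred+33 encoded string of the same
#' length as the sequence). A single read is a one-row `read_set`; every
#' read-level operation in the package is vectorised over the rows.
#'
#' @param read_id character vector of non-empty read identifiers.
#' @param sequence character vector of base sequences.
#' @param qualities list of integer vectors (or a single integer vector for
#'   one read) of per-base Phred scores in `[0, 93]`.
#' @param mate integer vector: 1, 2, or 0 (unpaired).
#' @return A `read_set` data frame.
#' @aliases read_set
#' @examples
#' r <- seq_record("r1", "ACGT", c(40, 40, 40, 40))
#' quality_scores(r)
#' @export
seq_record <- function(read_id, sequence, qualities, mate = 0L) {
  if (!is.list(qualities)) qualities <- list(as.integer(qualities))
  quality <- vapply(qualities, encode_phred33, character(1))
  new_read_set(as.character(read_id), toupper(as.character(sequence)),
               quality, as.integer(mate))
}

new_read_set <- function(read_id, sequence, quality, mate = 0L) {
  x <- data.frame(read_id = read_id, mate = rep_len(as.integer(mate),
                                                    length(read_id)),
                  sequence = sequence, quality = quality,
                  stringsAsFactors = FALSE)
  class(x) <- c("read_set", "data.frame")
  validate_read_set(x)
}

validate_read_set <- function(x) {
  if (nrow(x) == 0L) return(x)
  if (any(!nzchar(x$read_id))) stop("read_id must be non-empty")
  bad <- which(nchar(x$sequence) != nchar(x$quality))
  if (length(bad)) {
    stop(sprintf("read '%s' (record %d): sequence length %d != quality length %d",
                 x$read_id[bad[1]], bad[1], nchar(x$sequence[bad[1]]),
                 nchar(x$quality[bad[1]])))
  }
  x
}

encode_phred33 <- function(q) {
  q <- as.integer(q)
  if (length(q) == 0L) return("")
  if (anyNA(q) || any(q < 0L) || any(q > 93L))
    stop("Phred qualities must be integers in [0, 93]")
  intToUtf8(q + 33L)
}

#' @rdname seq_record
#' @param x a `read_set`.
#' @return `quality_scores()`: a list of integer Phred score vectors, one per
#'   read.
#' @export
quality_scores <- function(x) {
  lapply(x$quality, function(q) utf8ToInt(q) - 33L)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d read(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

# keep read_set class through row subsetting
#' @export
`[.read_set` <- function(x, i, ...) {
  y <- `[.data.frame`(as.data.frame(x), i, , drop = FALSE)
  rownames(y) <- NULL
  class(y) <- c("read_set", "data.frame")
  y
}

rbind_read_sets <- function(...) {
  y <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(y) <- NULL
  class(y) <- c("read_set", "data.frame")
  y
}

#' Paired read sets
#'
#' A `pair_set` holds mate-synchronised paired-end reads: a shared
#' `fragment_id` vector plus two parallel [read_set]s `mate1` and `mate2`.
#'
#' @param fragment_id character vector of fragment identifiers.
#' @param mate1,mate2 [read_set]s of equal length; mate designators are set to
#'   1 and 2.
#' @return A `pair_set` object.
#' @export
pair_set <- function(fragment_id, mate1, mate2) {
  stopifnot(nrow(mate1) == length(fragment_id),
            nrow(mate2) == length(fragment_id))
  mate1$mate <- rep(1L, nrow(mate1))
  mate2$mate <- rep(2L, nrow(mate2))
  structure(list(fragment_id = as.character(fragment_id),
                 mate1 = mate1, mate2 = mate2),
            class = "pair_set")
}

#' @rdname pair_set
#' @param x a `pair_set`.
#' @export
n_pairs <- function(x) length(x$fragment_id)

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set with %d read pair(s)\n", n_pairs(x)))
  invisible(x)
}

#' @export
`[.pair_set` <- function(x, i, ...) {
  pair_set(x$fragment_id[i], x$mate1[i], x$mate2[i])
}
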