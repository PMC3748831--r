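#' Read and write FASTQ files
#'
#' `read_fastq()` parses 4-line-per-record FASTQ into a [read_set], decoding
#' qualities as ASCII minus `phred_offset` and validating that every record's
#' sequence and quality strings have equal length and that every quality is in
#' `[0, 93]`. `write_fastq()` writes a [read_set] back out; reading a
#' well-formed file (bare `+` separator lines) and writing it at the same
#' offset is byte-identical.
#'
#' @param path path to a FASTQ file (plain text).
#' @param phred_offset quality encoding offset, 33 (default, Illumina 1.8+)
#'   or 64.
#' @return `read_fastq()`: a [read_set] preserving record order. Mate
#'   designators are parsed from trailing `/1` / `/2` on the read id.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1/1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
#' @export
read_fastq <- function(path, phred_offset = 33) {
  if (!phred_offset %in% c(33, 64)) stop("phred_offset must be 33 or 64")
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(new_read_set(character(), character(), character(), integer()))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("'%s': truncated FASTQ (%d lines, not a multiple of 4)",
                 path, length(lines)))
  hdr <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  seqs <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  plus <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  qual <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    stop(sprintf("record %d: header does not start with '@': '%s'",
                 bad[1], hdr[bad[1]]))
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf("record %d ('%s'): separator line does not start with '+'",
                 bad[1], hdr[bad[1]]))
  ids <- substring(hdr, 2L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("record %d ('%s'): sequence length %d != quality length %d",
                 bad[1], ids[bad[1]], nchar(seqs[bad[1]]), nchar(qual[bad[1]])))
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (length(codes) &&
      (min(codes) < phred_offset || max(codes) > phred_offset + 93L)) {
    per <- vapply(qual, function(q) {
      v <- utf8ToInt(q)
      length(v) > 0L && (min(v) < phred_offset || max(v) > phred_offset + 93L)
    }, logical(1))
    i <- which(per)[1]
    stop(sprintf("record %d ('%s'): quality score outside [0, 93] at offset %d",
                 i, ids[i], phred_offset))
  }
  if (phred_offset != 33) qual <- requote_phred(qual, phred_offset, 33)
  mate <- rep(0L, length(ids))
  mate[grepl("/1$", ids)] <- 1L
  mate[grepl("/2$", ids)] <- 2L
  new_read_set(ids, toupper(seqs), qual, mate)
}

requote_phred <- function(qual, from, to) {
  old <- intToUtf8(seq.int(from, from + 62L))  # Phred 0..62 covers +64 data
  new <- intToUtf8(seq.int(to, to + 62L))
  chartr(old, new, qual)
}

#' @rdname read_fastq
#' @param x a [read_set].
#' @export
write_fastq <- function(x, path, phred_offset = 33) {
  if (!phred_offset %in% c(33, 64)) stop("phred_offset must be 33 or 64")
  qual <- x$quality
  if (phred_offset != 33) qual <- requote_phred(qual, 33, phred_offset)
  n <- nrow(x)
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", x$read_id)
    lines[seq(2L, by = 4L, length.out = n)] <- x$sequence
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive fragment identifiers from read identifiers
#'
#' Strips a trailing `/1` or `/2` mate designator, then anything from the
#' first whitespace onward (Casava-style descriptions), in that order.
#'
#' @param ids character vector of read identifiers.
#' @return character vector of fragment identifiers.
#' @examples
#' fragment_ids(c("r1/1", "r2 1:N:0:ACGT"))
#' @export
fragment_ids <- function(ids) {
  sub("\\s.*$", "", sub("/[12]$", "", ids))
}

#' Read mate-synchronised paired FASTQ files
#'
#' Reads two FASTQ files whose records are mate-synchronised and pairs them
#' into a [pair_set]. Fragment identifiers are derived with [fragment_ids()];
#' any identifier mismatch after stripping, or a missing mate, is a hard
#' error naming the offending record.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @inheritParams read_fastq
#' @return A [pair_set].
#' @export
read_pairs <- function(path1, path2, phred_offset = 33) {
  r1 <- read_fastq(path1, phred_offset)
  r2 <- read_fastq(path2, phred_offset)
  if (nrow(r1) != nrow(r2)) {
    i <- min(nrow(r1), nrow(r2)) + 1L
    stop(sprintf("mate files of unequal length: no mate for record %d in '%s'",
                 i, if (nrow(r1) < nrow(r2)) path1 else path2))
  }
  f1 <- fragment_ids(r1$read_id)
  f2 <- fragment_ids(r2$read_id)
  bad <- which(f1 != f2)
  if (length(bad))
    stop(sprintf("read ID mismatch at record %d: '%s' vs '%s'",
                 bad[1], r1$read_id[bad[1]], r2$read_id[bad[1]]))
  pair_set(f1, r1, r2)
}

#' @rdname read_pairs
#' @param x a [pair_set].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @export
write_pairs <- function(x, prefix, phred_offset = 33) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  write_fastq(x$mate1, p1, phred_offset)
  write_fastq(x$mate2, p2, phred_offset)
  invisible(c(p1, p2))
}
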