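#' Read a fragment-to-transcript alignment table
#'
#' The pipeline consumes alignments as a minimal 4-column TSV with header
#' `fragment_id`, `transcript_id`, `concordant`, `sample_id` — the only
#' information fragment counting needs. `concordant` is parsed from
#' `{0, 1, true, false}` (case-insensitive); anything else, or an unknown
#' column, is a hard error.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `fragment_id`, `transcript_id`,
#'   `concordant` (logical), `sample_id`.
#' @seealso [read_sam_alignments()] for the optional SAM adapter.
#' @export
read_alignment_table <- function(path) {
  x <- read.delim(path, colClasses = "character", check.names = FALSE)
  want <- c("fragment_id", "transcript_id", "concordant", "sample_id")
  extra <- setdiff(names(x), want)
  if (length(extra))
    stop("unknown column(s) in alignment table: ", paste(extra, collapse = ", "))
  missing <- setdiff(want, names(x))
  if (length(missing))
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "))
  x <- x[want]
  x$concordant <- parse_bool(x$concordant, "concordant")
  x
}

parse_bool <- function(x, what) {
  v <- tolower(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true")] <- TRUE
  out[v %in% c("0", "false")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("unparsable %s value '%s' at row %d", what, x[bad[1]], bad[1]))
  out
}

#' @rdname read_alignment_table
#' @param x alignment data frame.
#' @export
write_alignment_table <- function(x, path) {
  y <- x[c("fragment_id", "transcript_id", "concordant", "sample_id")]
  y$concordant <- as.integer(y$concordant)
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce a SAM file to an alignment table
#'
#' Optional adapter for aligner output: keeps primary, mapped, first-in-pair
#' records and maps SAM flag bit `0x2` ("properly paired") to `concordant`.
#'
#' @param path path to a SAM file (plain text).
#' @param sample_id sample identifier to attach to every record.
#' @return data frame in [read_alignment_table()] layout.
#' @export
read_sam_alignments <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(fragment_id = character(), transcript_id = character(),
                      concordant = logical(), sample_id = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 11L)
  if (length(short)) stop(sprintf("malformed SAM record at line %d", short[1]))
  qname <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  rname <- vapply(f, `[[`, character(1), 3L)
  keep <- bitwAnd(flag, 0x4L) == 0L &           # mapped
    bitwAnd(flag, 0x100L) == 0L &               # primary
    bitwAnd(flag, 0x800L) == 0L &               # not supplementary
    bitwAnd(flag, 0x40L) > 0L &                 # first in pair
    rname != "*"
  data.frame(fragment_id = qname[keep],
             transcript_id = rname[keep],
             concordant = bitwAnd(flag[keep], 0x2L) > 0L,
             sample_id = sample_id)
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, no header). Columns 1, 2, 3, 4, 11 and 12 populate the
#' hit; the rest are ignored. Any row with a different number of columns is a
#' hard error naming the line.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `query_id`, `subject_id`, `pident`,
#'   `align_len`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), align_len = integer(),
                      evalue = numeric(), bitscore = numeric()))
  bad <- which(nf != 12L)
  if (length(bad))
    stop(sprintf("BLAST tabular line %d has %d columns (expected 12)",
                 bad[1], nf[bad[1]]))
  x <- read.delim(path, header = FALSE, quote = "", comment.char = "",
                  colClasses = c("character", "character", "numeric",
                                 "integer", rep("NULL", 6L),
                                 "numeric", "numeric"))
  names(x) <- c("query_id", "subject_id", "pident", "align_len",
                "evalue", "bitscore")
  if (any(x$pident < 0 | x$pident > 100))
    stop("pident outside [0, 100] in BLAST table")
  if (any(x$evalue < 0)) stop("negative e-value in BLAST table")
  x
}

#' Read a spike-in design table
#'
#' TSV with header columns `spike_id` and `known_mpe` (known molecules per
#' embryo, positive). Spike identifiers must be unique.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `spike_id`, `known_mpe`.
#' @export
read_spikein_design <- function(path) {
  x <- read.delim(path, check.names = FALSE)
  missing <- setdiff(c("spike_id", "known_mpe"), names(x))
  if (length(missing))
    stop("spike-in design lacks column(s): ", paste(missing, collapse = ", "))
  x <- data.frame(spike_id = as.character(x$spike_id),
                  known_mpe = as.numeric(x$known_mpe))
  if (anyNA(x$known_mpe) || any(x$known_mpe <= 0))
    stop("known_mpe must be positive")
  if (anyDuplicated(x$spike_id)) stop("duplicate spike_id in design")
  x
}

#' @rdname read_spikein_design
#' @param x spike-in design data frame.
#' @export
write_spikein_design <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
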