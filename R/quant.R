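#' Count fragments per transcript and sample
#'
#' Counts fragments (mate pairs), not individual mates. With
#' `concordant_only = TRUE` (the default, matching a directional protocol),
#' alignment records flagged discordant are skipped. A fragment aligned to
#' `m` transcripts within a sample contributes `1/m` to each, so per-sample
#' counts sum exactly to the number of counted fragments.
#'
#' @param alignments data frame of alignment records (`fragment_id`,
#'   `transcript_id`, `concordant`, `sample_id`), e.g. from
#'   [read_alignment_table()].
#' @param concordant_only count only concordant records (default `TRUE`).
#' @return data frame with columns `transcript_id`, `sample_id`, `count`.
#' @export
count_fragments <- function(alignments, concordant_only = TRUE) {
  dt <- data.table::as.data.table(
    alignments[c("fragment_id", "transcript_id", "concordant", "sample_id")])
  if (concordant_only) dt <- dt[dt$concordant == TRUE, ]  # nolint
  dt <- unique(dt[, c("fragment_id", "transcript_id", "sample_id"),
                  with = FALSE])
  if (nrow(dt) == 0L)
    return(data.frame(transcript_id = character(), sample_id = character(),
                      count = numeric()))
  fragment_id <- transcript_id <- sample_id <- w <- NULL  # for R CMD check
  dt[, w := 1 / .N, by = .(fragment_id, sample_id)]
  out <- dt[, .(count = sum(w)), by = .(transcript_id, sample_id)]
  data.table::setorder(out, transcript_id, sample_id)
  as.data.frame(out)
}

#' Total mapped fragments per sample
#'
#' @param counts data frame from [count_fragments()].
#' @return named numeric vector of per-sample totals (fractional multi-map
#'   contributions sum to one per fragment, so totals equal fragment counts).
#' @export
sample_totals <- function(counts) {
  out <- tapply(counts$count, counts$sample_id, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Compute FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm = count / ((length / 1e3) * (total / 1e6))`. Totals include every
#' counted fragment in the sample (transcripts and spike-ins alike).
#'
#' @param counts data frame from [count_fragments()].
#' @param lengths named numeric vector of transcript lengths in bases
#'   (all positive).
#' @param totals optional named per-sample totals; derived from `counts` by
#'   default. A zero or missing total for a sample is an error.
#' @return `counts` with an `fpkm` column appended.
#' @examples
#' cts <- data.frame(transcript_id = "T1", sample_id = "s0", count = 10)
#' compute_fpkm(cts, c(T1 = 1000), c(s0 = 1e6))$fpkm  # 10
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  if (is.null(totals)) totals <- sample_totals(counts)
  tot <- as.numeric(totals)[match(counts$sample_id, names(totals))]
  if (anyNA(tot) || any(tot <= 0))
    stop("every sample needs a positive total of mapped fragments")
  len <- as.numeric(lengths)[match(counts$transcript_id, names(lengths))]
  if (anyNA(len) || any(len <= 0))
    stop("every transcript needs a positive length")
  counts$fpkm <- counts$count / ((len / 1e3) * (tot / 1e6))
  counts
}

#' Assemble an expression matrix
#'
#' Builds the transcript-by-sample container used downstream: a
#' `SummarizedExperiment` with assays `counts` and `fpkm` (dense matrices,
#' zero where a transcript was not observed) and per-transcript `length` in
#' the row data. Rows cover every transcript in `lengths`, so undetected
#' transcripts appear with zero counts.
#'
#' @param counts data frame from [count_fragments()].
#' @param lengths named numeric vector of transcript lengths in bases.
#' @param totals optional per-sample totals passed to [compute_fpkm()].
#' @return a `SummarizedExperiment`.
#' @export
build_expression_matrix <- function(counts, lengths, totals = NULL) {
  missing <- setdiff(unique(counts$transcript_id), names(lengths))
  if (length(missing))
    stop("no length for transcript(s): ",
         paste(head(missing, 5), collapse = ", "))
  counts <- compute_fpkm(counts, lengths, totals)
  tx <- names(lengths)
  samples <- sort(unique(counts$sample_id))
  if (!length(samples)) samples <- "s0"
  cm <- matrix(0, length(tx), length(samples), dimnames = list(tx, samples))
  fm <- cm
  i <- cbind(match(counts$transcript_id, tx),
             match(counts$sample_id, samples))
  cm[i] <- counts$count
  fm[i] <- counts$fpkm
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cm, fpkm = fm),
    rowData = S4Vectors::DataFrame(length = as.numeric(lengths), row.names = tx))
}

#' Attach calibrated molecules-per-embryo to an expression matrix
#'
#' Maps the `fpkm` assay through per-sample standard curves into an `mpe`
#' assay (see [predict_mpe()]).
#'
#' @param mat a `SummarizedExperiment` from [build_expression_matrix()].
#' @param curves a single `standard_curve` (applied to every sample) or a
#'   named list of curves covering every sample.
#' @return `mat` with an `mpe` assay added.
#' @export
add_mpe <- function(mat, curves) {
  fm <- SummarizedExperiment::assay(mat, "fpkm")
  if (inherits(curves, "standard_curve"))
    curves <- stats::setNames(rep(list(curves), ncol(fm)), colnames(fm))
  missing <- setdiff(colnames(fm), names(curves))
  if (length(missing))
    stop("no standard curve for sample(s): ", paste(missing, collapse = ", "))
  mm <- fm
  for (s in colnames(fm)) mm[, s] <- predict_mpe(curves[[s]], fm[, s])
  SummarizedExperiment::assays(mat)$mpe <- mm
  mat
}

#' Count transcripts expressed above a threshold
#'
#' @param mat a calibrated `SummarizedExperiment` (with an `mpe` assay).
#' @param mpe_threshold expression threshold in molecules per embryo;
#'   transcripts qualify when their MPE strictly exceeds it.
#' @param require_any_sample if `TRUE` (default), one count of transcripts
#'   exceeding the threshold in at least one sample; if `FALSE`, a per-sample
#'   named vector of counts.
#' @param transcripts optional subset of transcript IDs to restrict to.
#' @return integer count, or named integer vector.
#' @export
count_expressed <- function(mat, mpe_threshold = 100,
                            require_any_sample = TRUE, transcripts = NULL) {
  if (!"mpe" %in% SummarizedExperiment::assayNames(mat))
    stop("expression matrix has no 'mpe' assay; apply calibration first")
  m <- SummarizedExperiment::assay(mat, "mpe")
  if (!is.null(transcripts))
    m <- m[rownames(m) %in% transcripts, , drop = FALSE]
  if (nrow(m) == 0L) {
    if (require_any_sample) return(0L)
    return(stats::setNames(rep(0L, ncol(m)), colnames(m)))
  }
  if (require_any_sample) sum(rowSums(m > mpe_threshold) > 0L)
  else colSums(m > mpe_threshold)
}

#' Long-format expression tables
#'
#' `expression_table()` flattens an expression matrix to a long data frame;
#' `expression_matrix_from_table()` rebuilds the `SummarizedExperiment` (used
#' by the command-line interface to pass expression between stages).
#'
#' @param mat a `SummarizedExperiment`.
#' @return a data frame with columns `transcript_id`, `sample_id`, `length`,
#'   `count`, `fpkm` and (if calibrated) `mpe`.
#' @export
expression_table <- function(mat) {
  an <- SummarizedExperiment::assayNames(mat)
  cm <- SummarizedExperiment::assay(mat, "counts")
  out <- data.frame(
    transcript_id = rep(rownames(cm), ncol(cm)),
    sample_id = rep(colnames(cm), each = nrow(cm)),
    length = rep(SummarizedExperiment::rowData(mat)$length, ncol(cm)),
    count = as.vector(cm),
    fpkm = as.vector(SummarizedExperiment::assay(mat, "fpkm")))
  if ("mpe" %in% an) out$mpe <- as.vector(SummarizedExperiment::assay(mat, "mpe"))
  out
}

#' @rdname expression_table
#' @param x a data frame in `expression_table()` layout.
#' @export
expression_matrix_from_table <- function(x) {
  lengths <- tapply(x$length, x$transcript_id, `[`, 1L)
  tx <- names(lengths)
  samples <- sort(unique(x$sample_id))
  shape <- function(col) {
    m <- matrix(0, length(tx), length(samples),
                dimnames = list(tx, samples))
    m[cbind(match(x$transcript_id, tx), match(x$sample_id, samples))] <- x[[col]]
    m
  }
  assays <- list(counts = shape("count"), fpkm = shape("fpkm"))
  if ("mpe" %in% names(x)) assays$mpe <- shape("mpe")
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(length = as.numeric(lengths),
                                   row.names = tx))
}
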