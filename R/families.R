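#' Filter BLAST hits by e-value and percent identity
#'
#' Keeps hits with `evalue < max_evalue` AND `pident > min_pident` — both
#' inequalities strict, so hits exactly at either threshold are dropped.
#'
#' @param hits data frame of BLAST hits, e.g. from [read_blast_tab()].
#' @param max_evalue e-value ceiling (default `5e-5`).
#' @param min_pident percent-identity floor (default 80).
#' @return the qualifying subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 5e-5, min_pident = 80) {
  out <- hits[hits$evalue < max_evalue & hits$pident > min_pident, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster transcripts into families from shared BLAST subjects
#'
#' Two transcripts belong to the same family when they share at least one
#' BLAST subject among the qualifying hits; families are the connected
#' components of this relation's transitive closure (single linkage) on the
#' bipartite query-subject incidence graph. Transcripts with no qualifying
#' hit form no family. Family identifiers are the lexicographically smallest
#' member ID, so output is deterministic and invariant under permutation of
#' the hit stream.
#'
#' @param hits data frame of qualifying hits (see [filter_hits()]) with
#'   columns `query_id` and `subject_id`.
#' @return a `transcript_families` object: a list of families, each with
#'   `family_id`, `members` (sorted transcript IDs) and `subjects` (sorted
#'   subject IDs), ordered by `family_id`.
#' @examples
#' h <- data.frame(query_id = c("T1", "T2", "T3"),
#'                 subject_id = c("P1", "P1", "P2"))
#' length(build_families(h))  # 2
#' @export
build_families <- function(hits) {
  edges <- unique(data.frame(query_id = as.character(hits$query_id),
                             subject_id = as.character(hits$subject_id)))
  if (nrow(edges) == 0L)
    return(structure(list(), class = "transcript_families"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("q|", edges$query_id),
               to = paste0("s|", edges$subject_id)),
    directed = FALSE)
  comp <- igraph::components(g)
  vs <- names(comp$membership)
  fams <- lapply(split(vs, comp$membership), function(v) {
    members <- sort(substring(v[startsWith(v, "q|")], 3L))
    subjects <- sort(substring(v[startsWith(v, "s|")], 3L))
    list(family_id = members[1], members = members, subjects = subjects)
  })
  fams <- fams[order(vapply(fams, `[[`, character(1), "family_id"))]
  names(fams) <- vapply(fams, `[[`, character(1), "family_id")
  structure(fams, class = "transcript_families")
}

#' @export
print.transcript_families <- function(x, ...) {
  cat(sprintf("transcript_families: %d family(ies), %d member transcript(s)\n",
              length(x), sum(lengths(lapply(x, `[[`, "members")))))
  invisible(x)
}

#' @rdname build_families
#' @param x a `transcript_families` object.
#' @param ... unused.
#' @return `as.data.frame()`: long data frame with columns `family_id`,
#'   `transcript_id`.
#' @export
as.data.frame.transcript_families <- function(x, ...) {
  data.frame(
    family_id = rep(vapply(x, `[[`, character(1), "family_id"),
                    vapply(x, function(f) length(f$members), integer(1))),
    transcript_id = unlist(lapply(x, `[[`, "members"), use.names = FALSE))
}

#' Summed family expression
#'
#' Sums member molecules-per-embryo per family and sample. Members absent
#' from the expression matrix contribute zero, with a warning.
#'
#' @param families a `transcript_families` object.
#' @param mat a calibrated `SummarizedExperiment` (with `mpe` assay), or a
#'   transcript-by-sample numeric matrix.
#' @param assay assay to sum when `mat` is a `SummarizedExperiment`
#'   (default `"mpe"`).
#' @return numeric matrix, families (by `family_id`) x samples.
#' @export
family_expression <- function(families, mat, assay = "mpe") {
  m <- if (is(mat, "SummarizedExperiment"))
    SummarizedExperiment::assay(mat, assay) else as.matrix(mat)
  ids <- vapply(families, `[[`, character(1), "family_id")
  out <- matrix(0, length(families), ncol(m),
                dimnames = list(ids, colnames(m)))
  absent <- character()
  for (i in seq_along(families)) {
    mem <- families[[i]]$members
    hit <- mem %in% rownames(m)
    if (!all(hit)) absent <- c(absent, mem[!hit])
    if (any(hit))
      out[i, ] <- colSums(m[mem[hit], , drop = FALSE])
  }
  if (length(absent))
    warning(sprintf("%d family member(s) absent from expression matrix (treated as 0), e.g. %s",
                    length(absent), absent[1]))
  out
}

#' Percent of the genome transcribed above a threshold
#'
#' Restricts to families whose summed expression strictly exceeds
#' `mpe_threshold` in at least one sample, takes the longest member of each,
#' and reports the summed longest-member lengths as a percentage of the
#' genome length.
#'
#' @inheritParams family_expression
#' @param lengths named numeric vector of transcript lengths in bases.
#' @param mpe_threshold threshold in molecules per embryo (default 100).
#' @param genome_length genome size in bases (default 450 Mbp, a sea-anemone
#'   scale genome).
#' @return percentage of the genome (0-100 scale).
#' @export
genome_fraction <- function(families, lengths, mat, mpe_threshold = 100,
                            genome_length = 450e6, assay = "mpe") {
  stopifnot(genome_length > 0)
  if (length(families) == 0L) return(0)
  fe <- family_expression(families, mat, assay = assay)
  qualifying <- rowSums(fe > mpe_threshold) > 0L
  if (!any(qualifying)) return(0)
  longest <- vapply(families[qualifying], function(f) {
    len <- lengths[f$members]
    len[is.na(len)] <- 0
    max(len)
  }, numeric(1))
  100 * sum(longest) / genome_length
}

#' Assembly summary statistics
#'
#' Mean length, fraction of transcripts strictly longer than 1 kb, N50 (the
#' largest length L such that transcripts of length >= L together cover at
#' least half the total assembly length) and a 100-bp-bin length histogram.
#'
#' @param lengths numeric vector of positive transcript lengths in bases.
#' @return an `assembly_stats` object: list with `n_transcripts`,
#'   `mean_length`, `n50`, `fraction_over_1kb`, `length_histogram` (named
#'   counts, names are bin lower bounds).
#' @examples
#' assembly_stats(c(100, 200, 300, 400, 1000))$n50  # 1000
#' @export
assembly_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("empty length list")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  bin <- 100 * (lengths %/% 100)
  hist <- table(factor(bin, levels = sort(unique(bin))))
  structure(list(n_transcripts = length(lengths),
                 mean_length = mean(lengths),
                 n50 = n50,
                 fraction_over_1kb = mean(lengths > 1000),
                 length_histogram = c(hist)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "assembly_stats: %d transcripts, mean %.2f bp, N50 %d bp, %.2f%% > 1 kb\n",
    x$n_transcripts, x$mean_length, as.integer(x$n50),
    100 * x$fraction_over_1kb))
  invisible(x)
}

#' Transcript-count filter ledger
#'
#' The summary table of how many distinct transcripts survive each hit and
#' expression filter: all transcripts; with >= 1 qualifying BLAST hit; above
#' an MPE threshold; above the threshold with >= 1 hit; and the number of
#' families built from the latter set.
#'
#' @param mat a calibrated `SummarizedExperiment`.
#' @param hits qualifying BLAST hits (already filtered).
#' @param mpe_threshold threshold in molecules per embryo (default 100).
#' @return data frame with columns `filter` and `n`.
#' @export
filter_ledger <- function(mat, hits, mpe_threshold = 100) {
  hit_tx <- unique(hits$query_id)
  n_all <- nrow(mat)
  n_hit <- length(hit_tx)
  n_mpe <- count_expressed(mat, mpe_threshold)
  n_both <- count_expressed(mat, mpe_threshold, transcripts = hit_tx)
  expressed <- rownames(mat)[rowSums(
    SummarizedExperiment::assay(mat, "mpe") > mpe_threshold) > 0L]
  fams <- build_families(hits[hits$query_id %in% expressed, , drop = FALSE])
  data.frame(
    filter = c("total_transcripts", "ge1_hit",
               sprintf("mpe_gt%g", mpe_threshold),
               sprintf("mpe_gt%g_ge1_hit", mpe_threshold),
               sprintf("families_mpe_gt%g_ge1_hit", mpe_threshold)),
    n = c(n_all, n_hit, n_mpe, n_both, length(fams)))
}
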