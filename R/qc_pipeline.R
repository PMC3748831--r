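#' Quality-control configuration
#'
#' Bundles every tunable of the two-phase QC cascade with the defaults used
#' throughout the package: adapter clipping (overlap >= 5, <= 10% mismatches),
#' canonical 25-mer contaminant screening (>= 1 shared k-mer), low-complexity
#' removal, a 13-base positional prefix trim, adaptive 3' trimming (5-base
#' window, mean quality >= 30) and a minimum surviving read length of 25
#' bases (reads shorter than a typical assembler k-mer are unusable).
#'
#' @param adapters character vector of adapter sequences to clip (may be
#'   empty).
#' @param contaminant_k k-mer length of the contaminant index (default 25).
#' @param min_shared_kmers shared canonical k-mers needed to flag a read
#'   (default 1).
#' @param min_adapter_overlap,max_adapter_mismatch_rate see [clip_adapter()].
#' @param prefix_trim leading bases removed from every read (default 13).
#' @param window,min_mean_quality see [adaptive_trim_3prime()].
#' @param min_length minimum read length kept after trimming (default 25).
#' @return a `qc_config` object.
#' @export
qc_config <- function(adapters = character(), contaminant_k = 25L,
                      min_shared_kmers = 1L, min_adapter_overlap = 5L,
                      max_adapter_mismatch_rate = 0.1, prefix_trim = 13L,
                      window = 5L, min_mean_quality = 30, min_length = 25L) {
  stopifnot(window >= 1, min_length >= 1, prefix_trim >= 0,
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate < 1,
            contaminant_k >= 1, min_shared_kmers >= 1, min_adapter_overlap >= 1)
  structure(list(adapters = toupper(as.character(adapters)),
                 contaminant_k = as.integer(contaminant_k),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate,
                 prefix_trim = as.integer(prefix_trim),
                 window = as.integer(window),
                 min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length)),
            class = "qc_config")
}

#' Run the two-phase quality-control cascade
#'
#' Phase 1 clips adapters from both mates and removes whole pairs in which
#' either mate matches the contaminant index (a contaminant fragment
#' contaminates both mates). Phase 2 removes low-complexity reads, trims the
#' positional prefix, applies adaptive 3' quality trimming, and removes reads
#' shorter than `min_length`. A pair whose mates both survive stays paired;
#' if exactly one mate is removed the survivor becomes an orphan. Every stage
#' is tallied in an attrition report.
#'
#' @param pairs a [pair_set].
#' @param config a [qc_config()].
#' @param contaminant_index optional `kmer_index` of contaminant references;
#'   `NULL` disables contaminant screening.
#' @return a list with elements `pairs` (surviving [pair_set]), `orphans`
#'   (a [read_set]) and `report` (a `qc_report` data frame; see Details).
#'
#' @details The report has one row per stage plus a `total` row, with columns
#' `stage`, `phase`, `pairs_in`, `orphans_in`, `reads_in`, `reads_removed`,
#' `pairs_out`, `orphans_out`, `reads_out`, `bases_in`, `bases_out`. Read
#' conservation holds at every stage: `reads_in == reads_out + reads_removed`
#' and `reads_out == 2 * pairs_out + orphans_out`.
#' @export
apply_qc_pipeline <- function(pairs, config = qc_config(),
                              contaminant_index = NULL) {
  stopifnot(inherits(pairs, "pair_set"), inherits(config, "qc_config"))
  st <- list(m1 = pairs$mate1, m2 = pairs$mate2,
             alive1 = rep(TRUE, n_pairs(pairs)),
             alive2 = rep(TRUE, n_pairs(pairs)))
  rows <- list()

  run_stage <- function(st, stage, phase, fn) {
    before <- qc_tally(st)
    st <- fn(st)
    after <- qc_tally(st)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, phase = phase,
      pairs_in = before$pairs, orphans_in = before$orphans,
      reads_in = before$reads,
      reads_removed = before$reads - after$reads,
      pairs_out = after$pairs, orphans_out = after$orphans,
      reads_out = after$reads,
      bases_in = before$bases, bases_out = after$bases)
    st
  }

  st <- run_stage(st, "adapter_clip", 1L, function(st) {
    for (ad in config$adapters) {
      st$m1 <- clip_adapter(st$m1, ad, config$min_adapter_overlap,
                            config$max_adapter_mismatch_rate)
      st$m2 <- clip_adapter(st$m2, ad, config$min_adapter_overlap,
                            config$max_adapter_mismatch_rate)
    }
    st
  })
  st <- run_stage(st, "contaminant_filter", 1L, function(st) {
    if (is.null(contaminant_index) || !length(contaminant_index$kmers))
      return(st)
    hit <- (filter_contaminant(st$m1, contaminant_index,
                               config$min_shared_kmers) |
            filter_contaminant(st$m2, contaminant_index,
                               config$min_shared_kmers)) &
      st$alive1 & st$alive2
    st$alive1[hit] <- FALSE
    st$alive2[hit] <- FALSE
    st
  })
  st <- run_stage(st, "low_complexity", 2L, function(st) {
    st$alive1 <- st$alive1 & !is_low_complexity(st$m1)
    st$alive2 <- st$alive2 & !is_low_complexity(st$m2)
    st
  })
  st <- run_stage(st, "prefix_trim", 2L, function(st) {
    st$m1 <- trim_prefix(st$m1, config$prefix_trim)
    st$m2 <- trim_prefix(st$m2, config$prefix_trim)
    st
  })
  st <- run_stage(st, "adaptive_trim", 2L, function(st) {
    st$m1 <- adaptive_trim_3prime(st$m1, config$window, config$min_mean_quality)
    st$m2 <- adaptive_trim_3prime(st$m2, config$window, config$min_mean_quality)
    st
  })
  st <- run_stage(st, "length_filter", 2L, function(st) {
    st$alive1 <- st$alive1 & nchar(st$m1$sequence) >= config$min_length
    st$alive2 <- st$alive2 & nchar(st$m2$sequence) >= config$min_length
    st
  })

  report <- do.call(rbind, rows)
  total <- data.frame(
    stage = "total", phase = NA_integer_,
    pairs_in = report$pairs_in[1], orphans_in = report$orphans_in[1],
    reads_in = report$reads_in[1],
    reads_removed = sum(report$reads_removed),
    pairs_out = report$pairs_out[nrow(report)],
    orphans_out = report$orphans_out[nrow(report)],
    reads_out = report$reads_out[nrow(report)],
    bases_in = report$bases_in[1],
    bases_out = report$bases_out[nrow(report)])
  report <- rbind(report, total)
  class(report) <- c("qc_report", "data.frame")

  both <- st$alive1 & st$alive2
  orphan1 <- st$alive1 & !st$alive2
  orphan2 <- st$alive2 & !st$alive1
  list(pairs = pair_set(pairs$fragment_id[both], st$m1[both], st$m2[both]),
       orphans = rbind_read_sets(st$m1[orphan1], st$m2[orphan2]),
       report = report)
}

qc_tally <- function(st) {
  npair <- sum(st$alive1 & st$alive2)
  norph <- sum(xor(st$alive1, st$alive2))
  list(pairs = npair, orphans = norph, reads = 2L * npair + norph,
       bases = sum(nchar(st$m1$sequence)[st$alive1]) +
         sum(nchar(st$m2$sequence)[st$alive2]))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC attrition report\n")
  print.data.frame(x)
  invisible(x)
}

#' Write / summarise a QC attrition report
#'
#' `write_qc_report()` writes the per-stage report as TSV.
#' `qc_phase_summary()` collapses it to the raw / end-of-phase-1 /
#' end-of-phase-2 ledger (pairs, reads and bases surviving, with percentages
#' of raw).
#'
#' @param report a `qc_report` from [apply_qc_pipeline()].
#' @param path output TSV path.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qc_report
#' @export
qc_phase_summary <- function(report) {
  stages <- report[report$stage != "total", ]
  p1 <- stages[max(which(stages$phase == 1L)), ]
  p2 <- stages[max(which(stages$phase == 2L)), ]
  raw <- stages[1L, ]
  out <- data.frame(
    checkpoint = c("raw", "qc_phase1", "qc_phase2"),
    pairs = c(raw$pairs_in, p1$pairs_out, p2$pairs_out),
    orphans = c(raw$orphans_in, p1$orphans_out, p2$orphans_out),
    reads = c(raw$reads_in, p1$reads_out, p2$reads_out),
    bases = c(raw$bases_in, p1$bases_out, p2$bases_out))
  out$pct_pairs <- 100 * out$pairs / out$pairs[1]
  out$pct_bases <- 100 * out$bases / out$bases[1]
  out
}
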