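#' Combined end-of-run report
#'
#' Stitches the stage outputs into a TSV bundle plus a human-readable
#' summary: QC attrition (per stage and per phase), standard-curve table
#' (one row per sample and method), per-transcript expression, per-sample
#' expressed-transcript counts at thresholds `> 0`, `> mpe_threshold`, and
#' `> mpe_threshold` with at least one qualifying BLAST hit, transcript
#' families and assembly statistics. Every number is re-derived from the
#' stage outputs; stages not supplied are marked absent in the summary.
#'
#' @param out_dir output directory (created if needed).
#' @param qc_report a `qc_report` from [apply_qc_pipeline()], or `NULL`.
#' @param curves list of `standard_curve`s (see [calibrate_all()]), or `NULL`.
#' @param expression a calibrated `SummarizedExperiment`, or `NULL`.
#' @param families a `transcript_families` object, or `NULL`.
#' @param stats an `assembly_stats` object, or `NULL`.
#' @param hits qualifying BLAST hits (for the hit-restricted expressed
#'   counts), or `NULL`.
#' @param mpe_threshold expression threshold for the report (default 100
#'   molecules per embryo).
#' @return invisibly, a named character vector of the files written.
#' @export
run_report <- function(out_dir, qc_report = NULL, curves = NULL,
                       expression = NULL, families = NULL, stats = NULL,
                       hits = NULL, mpe_threshold = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  summarise <- character()
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- path
  }

  if (!is.null(qc_report)) {
    emit("qc_report.tsv", qc_report)
    emit("qc_phases.tsv", qc_phase_summary(qc_report))
    tot <- qc_report[qc_report$stage == "total", ]
    summarise <- c(summarise, sprintf(
      "QC: %d pairs in -> %d pairs + %d orphans out (%.2f%% of reads, %.2f%% of bases kept)",
      tot$pairs_in, tot$pairs_out, tot$orphans_out,
      100 * tot$reads_out / max(1, tot$reads_in),
      100 * tot$bases_out / max(1, tot$bases_in)))
  } else summarise <- c(summarise, "QC: absent")

  if (!is.null(curves)) {
    ct <- curve_table(curves)
    emit("curves.tsv", ct)
    summarise <- c(summarise, sprintf(
      "Calibration: %d curve(s); R^2 range %.3f-%.3f",
      nrow(ct), min(ct$r_squared), max(ct$r_squared)))
  } else summarise <- c(summarise, "Calibration: absent")

  if (!is.null(expression)) {
    if (!is.null(curves)) {
      ct <- curve_table(curves)
      mism <- setdiff(colnames(expression), ct$sample_id)
      if (length(mism))
        stop("sample(s) in expression but without a curve: ",
             paste(mism, collapse = ", "))
    }
    emit("expression.tsv", expression_table(expression))
    if ("mpe" %in% SummarizedExperiment::assayNames(expression)) {
      hit_tx <- if (is.null(hits)) NULL else unique(hits$query_id)
      counts <- data.frame(
        sample_id = colnames(expression),
        expressed_gt0 = as.integer(count_expressed(expression, 0,
                                                   require_any_sample = FALSE)),
        expressed_gt_threshold = as.integer(
          count_expressed(expression, mpe_threshold,
                          require_any_sample = FALSE)))
      counts$expressed_gt_threshold_with_hit <- if (is.null(hit_tx))
        NA_integer_ else as.integer(
          count_expressed(expression, mpe_threshold,
                          require_any_sample = FALSE, transcripts = hit_tx))
      emit("expressed_counts.tsv", counts)
      summarise <- c(summarise, sprintf(
        "Expression: %d transcripts x %d samples; %d above %g MPE in >=1 sample",
        nrow(expression), ncol(expression),
        count_expressed(expression, mpe_threshold), mpe_threshold))
    }
  } else summarise <- c(summarise, "Expression: absent")

  if (!is.null(families)) {
    df <- as.data.frame(families)
    sizes <- table(df$family_id)
    fam_df <- data.frame(family_id = names(sizes),
                         n_members = as.integer(sizes))
    fam_df$members <- vapply(families[fam_df$family_id], function(f)
      paste(f$members, collapse = ","), character(1))
    if (!is.null(expression) &&
        "mpe" %in% SummarizedExperiment::assayNames(expression)) {
      fe <- family_expression(families, expression)
      colnames(fe) <- paste0("mpe_", colnames(fe))
      fam_df <- cbind(fam_df, as.data.frame(fe)[fam_df$family_id, ,
                                                drop = FALSE])
    }
    emit("families.tsv", fam_df)
    summarise <- c(summarise, sprintf("Families: %d", length(families)))
  } else summarise <- c(summarise, "Families: absent")

  if (!is.null(stats)) {
    emit("assembly_stats.tsv", data.frame(
      n_transcripts = stats$n_transcripts, mean_length = stats$mean_length,
      n50 = stats$n50, fraction_over_1kb = stats$fraction_over_1kb))
    emit("length_histogram.tsv", data.frame(
      bin_start = as.integer(names(stats$length_histogram)),
      count = as.integer(stats$length_histogram)))
    summarise <- c(summarise, sprintf(
      "Assembly: %d transcripts, mean %.2f bp, N50 %d",
      stats$n_transcripts, stats$mean_length, as.integer(stats$n50)))
  } else summarise <- c(summarise, "Assembly stats: absent")

  writeLines(summarise, file.path(out_dir, "summary.txt"))
  files[["summary.txt"]] <- file.path(out_dir, "summary.txt")
  invisible(files)
}
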