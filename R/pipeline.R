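#' Read and validate a pipeline configuration
#'
#' YAML configuration with nested sections `paths`, `qc`, `quant`,
#' `families`, `simulate`, plus top-level `seed` and `log_level`. Unknown
#' keys at any level are rejected; omitted keys fall back to the package
#' defaults documented on the respective functions.
#'
#' @param path path to a YAML file.
#' @return a named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- list(
    paths = c("r1", "r2", "adapters", "contaminants", "alignments",
              "transcripts", "spike_design", "blast", "out_dir"),
    qc = c("contaminant_k", "min_shared_kmers", "min_adapter_overlap",
           "max_adapter_mismatch_rate", "prefix_trim", "window",
           "min_mean_quality", "min_length"),
    quant = c("method", "scale", "concordant_only", "mpe_threshold"),
    families = c("max_evalue", "min_pident", "genome_length",
                 "mpe_threshold"),
    simulate = c("n_transcripts", "n_pairs", "n_samples", "n_spikes",
                 "decades", "read_len", "frag_len_mean",
                 "contaminant_fraction", "readthrough_rate",
                 "quality_profile"))
  top <- c(names(allowed), "seed", "log_level")
  bad <- setdiff(names(cfg), top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), names(allowed))) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad))
      stop(sprintf("unknown config key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

need_path <- function(cfg, key, stage) {
  p <- cfg$paths[[key]]
  if (is.null(p)) return(NULL)
  if (!file.exists(p))
    stop(sprintf("stage '%s': input file '%s' (%s) not found", stage, p, key))
  p
}

#' Run the full pipeline on declared inputs
#'
#' Executes QC -> quantification -> families -> report on whichever inputs
#' the configuration declares (each stage is skipped, and marked absent in
#' the report, when its inputs are not configured). Equivalent to running
#' the standalone stages by hand.
#'
#' @param config a `pipeline_config` from [read_pipeline_config()] (or an
#'   equivalent list).
#' @param out_dir output directory; overrides `paths$out_dir`.
#' @return invisibly, the list of report files written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- config
  if (is.null(out_dir)) out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  qc_rep <- NULL
  if (!is.null(cfg$paths$r1)) {
    r1 <- need_path(cfg, "r1", "qc")
    r2 <- need_path(cfg, "r2", "qc")
    if (is.null(r2)) stop("stage 'qc': r1 configured without r2")
    adapters <- if (!is.null(need_path(cfg, "adapters", "qc")))
      unname(read_fasta(cfg$paths$adapters)) else character()
    qcc <- do.call(qc_config, c(list(adapters = adapters), cfg$qc))
    idx <- NULL
    if (!is.null(need_path(cfg, "contaminants", "qc")))
      idx <- build_kmer_index(read_fasta(cfg$paths$contaminants),
                              qcc$contaminant_k)
    pipeline_log(cfg, "qc: reading %s / %s", r1, r2)
    res <- apply_qc_pipeline(read_pairs(r1, r2), qcc, idx)
    write_pairs(res$pairs, file.path(out_dir, "qc"))
    write_fastq(res$orphans, file.path(out_dir, "qc_orphans.fastq"))
    write_qc_report(res$report, file.path(out_dir, "qc_report.tsv"))
    qc_rep <- res$report
    pipeline_log(cfg, "qc: %d pairs, %d orphans out",
                 n_pairs(res$pairs), nrow(res$orphans))
  }

  mat <- NULL
  curves <- NULL
  if (!is.null(cfg$paths$alignments)) {
    aln <- read_alignment_table(need_path(cfg, "alignments", "quant"))
    tx <- need_path(cfg, "transcripts", "quant")
    if (is.null(tx)) stop("stage 'quant': transcripts FASTA required")
    lengths <- transcript_lengths(read_fasta(tx))
    concordant_only <- !isFALSE(cfg$quant$concordant_only)
    counts <- count_fragments(aln, concordant_only = concordant_only)
    mat <- build_expression_matrix(counts, lengths)
    des <- need_path(cfg, "spike_design", "quant")
    if (!is.null(des)) {
      design <- read_spikein_design(des)
      method <- if (is.null(cfg$quant$method)) "robust" else cfg$quant$method
      scl <- if (is.null(cfg$quant$scale)) "log10" else cfg$quant$scale
      curves <- calibrate_all(mat, design, method = method, scale = scl)
      mat <- add_mpe(mat, curves)
    }
    write.table(expression_table(mat), file.path(out_dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log(cfg, "quant: %d transcripts x %d samples",
                 nrow(mat), ncol(mat))
  }

  fams <- NULL
  stats <- NULL
  hits <- NULL
  if (!is.null(cfg$paths$blast)) {
    raw_hits <- read_blast_tab(need_path(cfg, "blast", "families"))
    fc <- cfg$families
    hits <- filter_hits(raw_hits,
                        max_evalue = fc$max_evalue %||% 5e-5,
                        min_pident = fc$min_pident %||% 80)
    fams <- build_families(hits)
    pipeline_log(cfg, "families: %d", length(fams))
  }
  if (!is.null(cfg$paths$transcripts) && file.exists(cfg$paths$transcripts))
    stats <- assembly_stats(transcript_lengths(read_fasta(cfg$paths$transcripts)))

  run_report(out_dir, qc_report = qc_rep, curves = curves, expression = mat,
             families = fams, stats = stats, hits = hits,
             mpe_threshold = cfg$quant$mpe_threshold %||% 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
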