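make_small_study <- function(seed = 101, n_tx = 15, samples = c("s0", "s1")) {
  tx <- generate_transcripts(n_tx, seed = seed)
  design <- generate_spikein_design(12, 4)
  spikes <- generate_spike_sequences(design, seed = seed + 1)
  mpe <- generate_expression_truth(names(tx), samples, 1, 3.5,
                                   seed = seed + 2)
  lengths <- c(transcript_lengths(tx), transcript_lengths(spikes))
  alns <- lapply(seq_along(samples), function(i) {
    sim <- simulate_reads(tx, mpe[, i], design, spikes, n_pairs = 3000,
                          sample_id = samples[i], seed = seed + 2 + i)
    simulate_alignments(sim$truth, seed = seed + 10 + i)
  })
  mat <- build_expression_matrix(count_fragments(do.call(rbind, alns)),
                                 lengths)
  curves <- calibrate_all(mat, design, method = "robust")
  list(mat = add_mpe(mat, curves), curves = curves, design = design,
       lengths = lengths, tx = tx)
}

test_that("the combined report bundles every stage with one curve per sample", {
  set.seed(201)
  study <- make_small_study()
  p <- clean_pairs(20)
  qc <- apply_qc_pipeline(p, qc_config())
  hits <- data.frame(query_id = rownames(study$mat)[1:6],
                     subject_id = rep(c("P1", "P2"), 3),
                     pident = 90, align_len = 100, evalue = 1e-30,
                     bitscore = 100)
  fams <- build_families(hits)
  stats <- assembly_stats(transcript_lengths(study$tx))
  out <- withr::local_tempdir()
  files <- run_report(out, qc_report = qc$report, curves = study$curves,
                      expression = study$mat, families = fams, stats = stats,
                      hits = hits)
  expect_true(all(file.exists(files)))
  curves <- read.delim(files[["curves.tsv"]])
  expect_identical(nrow(curves), 2L)
  expect_setequal(curves$sample_id, c("s0", "s1"))
  counts <- read.delim(files[["expressed_counts.tsv"]])
  expect_identical(names(counts),
                   c("sample_id", "expressed_gt0", "expressed_gt_threshold",
                     "expressed_gt_threshold_with_hit"))
  # report numbers re-derive from the stage outputs
  expect_equal(counts$expressed_gt0,
               unname(count_expressed(study$mat, 0,
                                      require_any_sample = FALSE)))
  expect_true(all(counts$expressed_gt_threshold_with_hit <=
                    counts$expressed_gt_threshold))
})

test_that("partial reports mark missing stages absent", {
  p <- clean_pairs(5)
  qc <- apply_qc_pipeline(p, qc_config())
  out <- withr::local_tempdir()
  run_report(out, qc_report = qc$report)
  summary <- readLines(file.path(out, "summary.txt"))
  expect_true(any(grepl("^QC: ", summary)))
  expect_true(any(grepl("Expression: absent", summary)))
  expect_true(any(grepl("Families: absent", summary)))
})

test_that("expression samples without a curve are rejected", {
  set.seed(202)
  study <- make_small_study()
  out <- withr::local_tempdir()
  expect_error(run_report(out, curves = study$curves["s0"],
                          expression = study$mat),
               "without a curve")
})

test_that("pipeline configuration rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 1", "qc:", "  min_length: 30"), f)
  cfg <- read_pipeline_config(f)
  expect_identical(cfg$qc$min_length, 30L)
  writeLines(c("seed: 1", "qc:", "  minimum_length: 30"), f)
  expect_error(read_pipeline_config(f), "unknown config key.*qc")
  writeLines("bogus_section: 1", f)
  expect_error(read_pipeline_config(f), "bogus_section")
})

test_that("run_pipeline drives QC, quantification and reporting end to end", {
  dir <- withr::local_tempdir()
  tx <- generate_transcripts(10, seed = 301)
  design <- generate_spikein_design(10, 4)
  spikes <- generate_spike_sequences(design, seed = 302)
  mpe <- generate_expression_truth(names(tx), "s0", 1.5, 3.5, seed = 303)
  contam <- generate_transcripts(2, mean_length = 1500, seed = 304,
                                 prefix = "RRNA")
  sim <- simulate_reads(tx, mpe[, 1], design, spikes, n_pairs = 1500,
                        contaminant_refs = contam, contaminant_fraction = 0.05,
                        seed = 305)
  write_pairs(sim$pairs, file.path(dir, "reads"))
  write_fasta(c(tx, spikes), file.path(dir, "transcripts.fasta"))
  write_fasta(contam, file.path(dir, "contaminants.fasta"))
  write_spikein_design(design, file.path(dir, "design.tsv"))
  aln <- simulate_alignments(sim$truth, seed = 306)
  write_alignment_table(aln, file.path(dir, "aln.tsv"))
  writeLines(c(
    "seed: 1", "log_level: quiet", "paths:",
    paste0("  r1: ", file.path(dir, "reads_R1.fastq")),
    paste0("  r2: ", file.path(dir, "reads_R2.fastq")),
    paste0("  contaminants: ", file.path(dir, "contaminants.fasta")),
    paste0("  alignments: ", file.path(dir, "aln.tsv")),
    paste0("  transcripts: ", file.path(dir, "transcripts.fasta")),
    paste0("  spike_design: ", file.path(dir, "design.tsv")),
    paste0("  out_dir: ", file.path(dir, "out"))), file.path(dir, "cfg.yaml"))
  cfg <- read_pipeline_config(file.path(dir, "cfg.yaml"))
  files <- run_pipeline(cfg)
  expect_true(file.exists(file.path(dir, "out", "qc_report.tsv")))
  expect_true(file.exists(file.path(dir, "out", "expression.tsv")))
  expect_true(file.exists(file.path(dir, "out", "curves.tsv")))
  expr <- read.delim(file.path(dir, "out", "expression.tsv"))
  expect_true("mpe" %in% names(expr))
  # a missing configured input is a hard error naming the stage
  cfg$paths$alignments <- file.path(dir, "nope.tsv")
  expect_error(run_pipeline(cfg), "quant")
})
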