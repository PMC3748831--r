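test_that("clean pairs pass the cascade untouched by filters", {
  set.seed(5)
  p <- clean_pairs(10)
  res <- apply_qc_pipeline(p, qc_config())
  expect_identical(n_pairs(res$pairs), 10L)
  expect_identical(nrow(res$orphans), 0L)
  tot <- res$report[res$report$stage == "total", ]
  expect_identical(tot$reads_removed, 0L)
  # prefix trim still removes 13 bases per read
  expect_identical(tot$bases_out, 20L * 87L)
})

test_that("a low-complexity mate orphans its partner", {
  set.seed(6)
  p <- clean_pairs(1)
  p$mate2$sequence <- strrep("A", 100)
  res <- apply_qc_pipeline(p, qc_config())
  expect_identical(n_pairs(res$pairs), 0L)
  expect_identical(nrow(res$orphans), 1L)
  expect_identical(res$orphans$mate, 1L)
  lc <- res$report[res$report$stage == "low_complexity", ]
  expect_identical(lc$reads_removed, 1L)
  expect_identical(lc$orphans_out, 1L)
})

test_that("contaminant pairs are removed whole, never orphaned", {
  set.seed(8)
  refs <- setNames(random_seqs(1000), "rrna")
  idx <- build_kmer_index(refs, 25)
  p <- clean_pairs(2)
  p$mate1$sequence[1] <- substr(refs, 1, 100)
  p$mate2$sequence[1] <- rc_chr(substr(refs, 200, 299))
  res <- apply_qc_pipeline(p, qc_config(), idx)
  expect_identical(n_pairs(res$pairs), 1L)
  expect_identical(nrow(res$orphans), 0L)
  ct <- res$report[res$report$stage == "contaminant_filter", ]
  expect_identical(ct$reads_removed, 2L)
})

test_that("read conservation holds at every stage and overall", {
  set.seed(10)
  refs <- setNames(random_seqs(c(800, 700)), c("c1", "c2"))
  idx <- build_kmer_index(refs, 25)
  p <- clean_pairs(300, q = 30)
  # plant assorted failure modes
  p$mate1$sequence[1:20] <- vapply(nchar(p$mate1$sequence[1:20]),
                                   function(L) substr(refs[[1]], 1, L), "")
  p$mate2$sequence[21:40] <- strrep("AC", 50)
  p$mate1$quality[41:60] <- strrep("#", 100)   # Phred 2 everywhere
  res <- apply_qc_pipeline(p, qc_config(adapters = "AGATCGGAAGAGC"), idx)
  rep <- res$report
  expect_true(all(rep$reads_in == rep$reads_out + rep$reads_removed))
  expect_true(all(rep$reads_out == 2L * rep$pairs_out + rep$orphans_out))
  expect_true(all(rep$reads_in == 2L * rep$pairs_in + rep$orphans_in))
  expect_true(all(rep$bases_out <= rep$bases_in))
  # stages compose: each stage's inputs are the previous stage's outputs
  stg <- rep[rep$stage != "total", ]
  expect_identical(stg$reads_in[-1], stg$reads_out[-nrow(stg)])
  tot <- rep[rep$stage == "total", ]
  expect_identical(tot$reads_in,
                   2L * n_pairs(res$pairs) + nrow(res$orphans) +
                     tot$reads_removed)
})

test_that("the cascade equals a monolithic per-read re-implementation", {
  set.seed(12)
  n <- 150
  refs <- setNames(random_seqs(600), "rrna")
  idx <- build_kmer_index(refs, 25)
  adapter <- "AGATCGGAAGAGC"
  p <- clean_pairs(n, q = 30)
  # randomly degrade reads: contaminants, low complexity, quality decay,
  # planted adapter suffixes
  for (i in sample(n, 25)) {
    start <- sample(400, 1)
    p$mate1$sequence[i] <- substr(refs, start, start + 99)
  }
  for (i in sample(n, 25)) p$mate2$sequence[i] <- strrep("GT", 50)
  for (i in sample(n, 30)) {
    q <- c(rep(35, 50), pmax(2, 35 - cumsum(sample(0:3, 50, TRUE))))
    p$mate2$quality[i] <- intToUtf8(q + 33L)
  }
  for (i in sample(n, 20)) {
    keep <- sample(40:80, 1)
    p$mate1$sequence[i] <- paste0(substr(p$mate1$sequence[i], 1, keep),
                                  substr(adapter, 1, 100 - keep))
  }
  cfg <- qc_config(adapters = adapter)
  res <- apply_qc_pipeline(p, cfg, idx)

  # independent per-read oracle of the whole cascade
  oracle_read <- function(s, q) {
    keep <- oracle_clip_len(s, adapter, cfg$min_adapter_overlap,
                            cfg$max_adapter_mismatch_rate)
    s <- substr(s, 1, keep)
    q <- q[seq_len(keep)]
    list(s = s, q = q,
         contaminant = oracle_shared_count(s, idx$kmers, 25) >= 1)
  }
  oracle_phase2 <- function(s, q) {
    bases <- setdiff(unique(strsplit(s, "")[[1]]), "N")
    if (length(bases) <= 2) return(NULL)
    s <- substring(s, cfg$prefix_trim + 1)
    q <- q[-seq_len(min(cfg$prefix_trim, length(q)))]
    keep <- oracle_trim_len(q, cfg$window, cfg$min_mean_quality)
    if (keep < cfg$min_length) return(NULL)
    substr(s, 1, keep)
  }
  survivors <- character()
  orphans <- character()
  qs1 <- quality_scores(p$mate1)
  qs2 <- quality_scores(p$mate2)
  for (i in seq_len(n)) {
    a <- oracle_read(p$mate1$sequence[i], qs1[[i]])
    b <- oracle_read(p$mate2$sequence[i], qs2[[i]])
    if (a$contaminant || b$contaminant) next
    s1 <- oracle_phase2(a$s, a$q)
    s2 <- oracle_phase2(b$s, b$q)
    if (!is.null(s1) && !is.null(s2)) {
      survivors <- c(survivors, p$fragment_id[i])
    } else if (!is.null(s1)) orphans <- c(orphans, p$mate1$read_id[i])
    else if (!is.null(s2)) orphans <- c(orphans, p$mate2$read_id[i])
  }
  expect_identical(res$pairs$fragment_id, survivors)
  expect_setequal(res$orphans$read_id, orphans)
})

test_that("phase summary reproduces the attrition checkpoints", {
  set.seed(14)
  p <- clean_pairs(50, q = 30)
  p$mate2$sequence[1:5] <- strrep("A", 100)
  res <- apply_qc_pipeline(p, qc_config())
  ph <- qc_phase_summary(res$report)
  expect_identical(ph$checkpoint, c("raw", "qc_phase1", "qc_phase2"))
  expect_identical(ph$pairs[1], 50L)
  expect_identical(ph$pairs[3], n_pairs(res$pairs))
  expect_identical(ph$orphans[3], nrow(res$orphans))
  expect_equal(ph$pct_pairs[1], 100)
})
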