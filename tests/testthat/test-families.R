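hit <- function(q, s, evalue = 1e-50, pident = 95) {
  data.frame(query_id = q, subject_id = s, pident = pident,
             align_len = 100L, evalue = evalue, bitscore = 200)
}

test_that("hit filtering applies both thresholds strictly", {
  h <- rbind(hit("T1", "P1", evalue = 1e-6, pident = 85),
             hit("T2", "P1", evalue = 5e-5, pident = 85),   # at e ceiling
             hit("T3", "P1", evalue = 1e-6, pident = 80),   # at pident floor
             hit("T4", "P1", evalue = 4.9e-5, pident = 80.01))
  kept <- filter_hits(h, 5e-5, 80)
  expect_setequal(kept$query_id, c("T1", "T4"))
})

test_that("families form by single linkage over shared subjects", {
  f <- build_families(data.frame(query_id = c("T1", "T2", "T3"),
                                 subject_id = c("P1", "P1", "P2")))
  expect_identical(members_of(f), list(T1 = c("T1", "T2"), T3 = "T3"))
  # transitive linking through a shared subject chain
  f <- build_families(data.frame(query_id = c("T1", "T2", "T2", "T3"),
                                 subject_id = c("P1", "P1", "P2", "P2")))
  expect_identical(members_of(f), list(T1 = c("T1", "T2", "T3")))
  expect_identical(f$T1$subjects, c("P1", "P2"))
  # singleton
  f <- build_families(data.frame(query_id = "T9", subject_id = "P1"))
  expect_identical(members_of(f), list(T9 = "T9"))
  expect_length(build_families(data.frame(query_id = character(),
                                          subject_id = character())), 0L)
})

test_that("clustering matches the pairwise-closure oracle and ignores order", {
  set.seed(37)
  for (i in 1:40) {
    h <- random_hits(60, 15)
    f <- build_families(h)
    expect_identical(unname(members_of(f)), oracle_families(h))
    sh <- h[sample(nrow(h)), ]
    expect_identical(build_families(sh), f)
  }
})

test_that("relaxing thresholds never increases the family count", {
  set.seed(41)
  h <- random_hits(100, 20)
  h$evalue <- 10^runif(nrow(h), -80, -3)
  h$pident <- runif(nrow(h), 60, 100)
  strict <- build_families(filter_hits(h, 5e-5, 80))
  # relaxed thresholds admit more hits: components merge or grow, never split
  relaxed <- build_families(filter_hits(h, 1e-3, 70))
  expect_lte(length(relaxed), length(strict) +
               (length(unique(filter_hits(h, 1e-3, 70)$query_id)) -
                length(unique(filter_hits(h, 5e-5, 80)$query_id))))
  # with a fixed hit set, fewer families can only come from merging
  expect_true(all(lengths(members_of(strict)) >= 1))
})

test_that("family expression sums member MPE per sample", {
  m <- matrix(c(600, 400, 30, 70), 2, 2,
              dimnames = list(c("T1", "T2"), c("s0", "s1")))
  fams <- build_families(data.frame(query_id = c("T1", "T2"),
                                    subject_id = "P1"))
  fe <- family_expression(fams, m)
  expect_equal(fe["T1", ], c(s0 = 1000, s1 = 100))
  fams2 <- build_families(data.frame(query_id = c("T1", "T2", "TX"),
                                     subject_id = c("P1", "P1", "P1")))
  expect_warning(fe2 <- family_expression(fams2, m), "absent")
  expect_equal(unname(fe2[1, "s0"]), 1000)
})

test_that("genome fraction sums longest members of expressed families", {
  fams <- build_families(data.frame(query_id = c("T1", "T2", "T3"),
                                    subject_id = c("P1", "P1", "P2")))
  lengths <- c(T1 = 450, T2 = 200, T3 = 2000)
  m <- matrix(c(500, 400, 50), 3, 1, dimnames = list(names(lengths), "s0"))
  # only family {T1,T2} exceeds 100 MPE (900 summed); longest member 450
  expect_equal(genome_fraction(fams, lengths, m, 100, 450e3), 0.1)
  expect_equal(genome_fraction(fams, lengths, m, 1e6, 450e3), 0)
  # both families qualify at threshold 0: (450 + 2000) / 1e6
  m2 <- matrix(c(500, 400, 1000), 3, 1, dimnames = list(names(lengths), "s0"))
  fams2 <- build_families(data.frame(query_id = c("T1", "T2", "T3"),
                                     subject_id = c("P1", "P1", "P2")))
  lengths2 <- c(T1 = 1000, T2 = 100, T3 = 2000)
  expect_equal(genome_fraction(fams2, lengths2, m2, 0, 1e6), 0.3)
  # monotone non-increasing in the threshold
  set.seed(43)
  thr <- sort(runif(6, 0, 2000))
  gf <- vapply(thr, function(t)
    genome_fraction(fams2, lengths2, m2, t, 1e6), numeric(1))
  expect_true(all(diff(gf) <= 0))
})

test_that("assembly statistics match the cumulative-sum definitions", {
  st <- assembly_stats(c(100, 200, 300, 400, 1000))
  expect_equal(st$mean_length, 400)
  expect_equal(st$fraction_over_1kb, 0)
  expect_equal(st$n50, 1000)  # 1000 alone covers half of 2000
  expect_equal(assembly_stats(500)$n50, 500)
  expect_equal(assembly_stats(rep(750, 9))$n50, 750)
  expect_error(assembly_stats(numeric()), "empty")
  expect_error(assembly_stats(c(10, -5)), "positive")
  set.seed(47)
  lens <- sample(50:3000, 200, TRUE)
  st <- assembly_stats(lens)
  expect_equal(st$n50, oracle_n50(lens))
  expect_equal(st$fraction_over_1kb, mean(lens > 1000))
  expect_identical(sum(st$length_histogram), 200L)
  # histogram bin consistent with the > 1 kb fraction up to the 1000 boundary
  expect_equal(sum(st$length_histogram[as.integer(names(st$length_histogram))
                                       >= 1000]),
               sum(lens >= 1000))
})

test_that("the filter ledger tallies transcripts surviving each filter", {
  m <- matrix(c(500, 50, 150, 0), 4, 1,
              dimnames = list(c("T1", "T2", "T3", "T4"), "s0"))
  mat <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m, fpkm = m, mpe = m))
  hits <- hit(c("T1", "T2"), c("P1", "P1"))
  led <- filter_ledger(mat, hits, 100)
  expect_equal(led$n[led$filter == "total_transcripts"], 4)
  expect_equal(led$n[led$filter == "ge1_hit"], 2)
  expect_equal(led$n[led$filter == "mpe_gt100"], 2)          # T1, T3
  expect_equal(led$n[led$filter == "mpe_gt100_ge1_hit"], 1)  # T1
  expect_equal(led$n[led$filter == "families_mpe_gt100_ge1_hit"], 1)
})
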