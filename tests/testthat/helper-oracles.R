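# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (literal simulations of the definitions) and kept
# separate from the package's implementation paths.

# Step-by-step simulation of the sliding-window 3' trimmer: drop the final
# base while the last-`window` mean is below the threshold; once fewer than
# `window` bases remain, test the mean of what is left once.
oracle_trim_len <- function(q, window, thr) {
  repeat {
    n <- length(q)
    if (n < window) break
    if (mean(q[(n - window + 1):n]) >= thr) return(n)
    q <- q[-n]
  }
  if (length(q) == 0L) return(0L)
  if (mean(q) < thr) 0L else length(q)
}

# Overlap-scan adapter clipping oracle: try every truncation point left to
# right, compare the adapter prefix to the read suffix.
oracle_clip_len <- function(s, adapter, min_overlap, rate) {
  n <- nchar(s)
  m <- nchar(adapter)
  sv <- strsplit(s, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (p in seq_len(n)) {
    L <- min(n - p + 1L, m)
    if (L < min_overlap) next
    a <- av[seq_len(L)]
    b <- sv[p:(p + L - 1L)]
    mism <- sum(a != b | a == "N" | b == "N")
    if (mism <= rate * L + 1e-9) return(p - 1L)
  }
  n
}

rc_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# enumerate all k-mer windows, drop those with N, canonicalise by hand
oracle_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1L), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    out <- c(out, pmin(km, rc_chr(km)))
  }
  unique(out)
}

oracle_shared_count <- function(s, kmer_set, k) {
  n <- nchar(s)
  if (n < k) return(0L)
  km <- substring(s, 1:(n - k + 1L), k:n)
  ok <- !grepl("[^ACGT]", km)
  sum(pmin(km[ok], rc_chr(km[ok])) %in% kmer_set)
}

# O(n^2) pairwise transitive-closure clustering oracle: adjacency = shares a
# subject; closure by repeated boolean multiplication; returns the sorted
# list of sorted member sets.
oracle_families <- function(edges) {
  edges <- unique(edges[c("query_id", "subject_id")])
  q <- sort(unique(edges$query_id))
  s <- unique(edges$subject_id)
  if (!length(q)) return(list())
  M <- matrix(0, length(q), length(s), dimnames = list(q, s))
  M[cbind(match(edges$query_id, q), match(edges$subject_id, s))] <- 1
  A <- (M %*% t(M)) > 0
  repeat {
    A2 <- ((A %*% A) > 0) | A
    if (identical(A2, A)) break
    A <- A2
  }
  comps <- unique(lapply(seq_along(q), function(i) q[A[i, ]]))
  comps[order(vapply(comps, `[`, character(1), 1))]
}

members_of <- function(fams) lapply(unclass(fams), `[[`, "members")

# exhaustive cumulative-sum N50: largest L among the observed lengths such
# that lengths >= L sum to at least half the assembly
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
  min(lengths)
}

random_seqs <- function(lens) {
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

random_reads <- function(n, len_min = 20, len_max = 150, qmax = 45,
                         prefix = "r") {
  lens <- sample(len_min:len_max, n, replace = TRUE)
  seq_record(paste0(prefix, seq_len(n)), random_seqs(lens),
             lapply(lens, function(L) sample(0:qmax, L, replace = TRUE)))
}

# paired reads with uniform high quality
clean_pairs <- function(n, len = 100, q = 38) {
  lens <- rep(len, n)
  m1 <- seq_record(sprintf("f%d/1", 1:n), random_seqs(lens),
                   lapply(lens, function(L) rep(q, L)), mate = 1L)
  m2 <- seq_record(sprintf("f%d/2", 1:n), random_seqs(lens),
                   lapply(lens, function(L) rep(q, L)), mate = 2L)
  pair_set(sprintf("f%d", 1:n), m1, m2)
}

random_hits <- function(n_tx_max = 200, n_subj_max = 50) {
  n_tx <- sample(2:n_tx_max, 1)
  n_subj <- sample(1:n_subj_max, 1)
  n_hits <- sample(1:(3 * n_tx), 1)
  data.frame(
    query_id = sprintf("T%03d", sample(n_tx, n_hits, replace = TRUE)),
    subject_id = sprintf("P%02d", sample(n_subj, n_hits, replace = TRUE)))
}
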