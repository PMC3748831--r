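#' Generate random transcript sequences
#'
#' Random transcripts with log-normal lengths (mean `mean_length`, default
#' 600 bp with a tail past 1 kb — the regime typical of short-read de novo
#' assemblies). Deterministic under `seed`.
#'
#' @param n number of transcripts (>= 1).
#' @param mean_length target mean length in bases (default 600).
#' @param sdlog log-scale standard deviation of the length distribution
#'   (default 0.7).
#' @param min_length lower bound on lengths in bases (default 100).
#' @param seed RNG seed.
#' @param prefix transcript ID prefix.
#' @return named character vector of sequences (`TX00001`, ...).
#' @export
generate_transcripts <- function(n, mean_length = 600, sdlog = 0.7,
                                 min_length = 100, seed = NULL,
                                 prefix = "TX") {
  stopifnot(n >= 1, mean_length > 0, sdlog >= 0, min_length >= 1)
  local_seed(seed, {
    meanlog <- log(mean_length) - sdlog^2 / 2
    lens <- pmax(min_length, round(rlnorm(n, meanlog, sdlog)))
    seqs <- random_dna(lens)
    names(seqs) <- sprintf("%s%05d", prefix, seq_len(n))
    seqs
  })
}

random_dna <- function(lens) {
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a spike-in design
#'
#' Known concentrations log-evenly spaced over `decades` orders of magnitude
#' (default 6) starting at `min_mpe` molecules per embryo; 92 points by
#' default, the size of an ERCC-style two-mix design.
#'
#' @param n_points number of spike-ins (>= 3; default 92).
#' @param decades orders of magnitude spanned (default 6; 0 gives a
#'   degenerate all-equal design, which calibration will reject).
#' @param min_mpe lowest concentration in molecules per embryo (default 1).
#' @return data frame with columns `spike_id`, `known_mpe`.
#' @export
generate_spikein_design <- function(n_points = 92, decades = 6, min_mpe = 1) {
  stopifnot(n_points >= 3, decades >= 0, min_mpe > 0)
  data.frame(
    spike_id = sprintf("SPIKE-%03d", seq_len(n_points)),
    known_mpe = 10^seq(log10(min_mpe), log10(min_mpe) + decades,
                       length.out = n_points))
}

#' @rdname generate_spikein_design
#' @param design a spike-in design data frame.
#' @param min_length,max_length spike-in sequence length range in bases
#'   (defaults 250-2000, the ERCC range).
#' @param seed RNG seed.
#' @return `generate_spike_sequences()`: named character vector of spike-in
#'   sequences keyed by `spike_id`.
#' @export
generate_spike_sequences <- function(design, min_length = 250,
                                     max_length = 2000, seed = NULL) {
  local_seed(seed, {
    lens <- sample(seq.int(min_length, max_length), nrow(design),
                   replace = TRUE)
    stats::setNames(random_dna(lens), design$spike_id)
  })
}

#' Draw ground-truth expression levels
#'
#' Per-transcript, per-sample true molecules per embryo, log-uniform over
#' `[10^min_log10, 10^max_log10]`, independent across samples.
#'
#' @param transcript_ids character vector of transcript IDs.
#' @param sample_ids character vector of sample IDs (e.g. five timepoints).
#' @param min_log10,max_log10 log10 bounds of true MPE (defaults 0 and 4).
#' @param seed RNG seed.
#' @return numeric matrix, transcripts x samples.
#' @export
generate_expression_truth <- function(transcript_ids, sample_ids,
                                      min_log10 = 0, max_log10 = 4,
                                      seed = NULL) {
  local_seed(seed, {
    matrix(10^runif(length(transcript_ids) * length(sample_ids),
                    min_log10, max_log10),
           length(transcript_ids), length(sample_ids),
           dimnames = list(transcript_ids, sample_ids))
  })
}

#' Simulate paired-end reads with known truth
#'
#' Emulates a directional paired-end protocol over a transcript pool
#' (assembled transcripts plus optional spike-ins): fragments are drawn with
#' probability proportional to `abundance * length` (so per-transcript counts
#' are multinomial given the library size, i.e. Poisson conditioned on
#' depth); mates are read from opposite fragment ends, mate 2 reverse
#' complemented. Planted failure modes, each recorded in the returned truth
#' table: adapter read-through (fragments shorter than the read length embed
#' the adapter at a known position in both mates), verbatim contaminant
#' pairs copied from `contaminant_refs`, and a declining 3' quality profile.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param abundances named numeric vector of true molecules per embryo for
#'   `transcripts` (this sample).
#' @param spike_design optional spike-in design (`spike_id`, `known_mpe`);
#'   spike-ins enter the pool at their design abundance.
#' @param spike_sequences named character vector of spike-in sequences
#'   (generated via [generate_spike_sequences()] when `NULL` and a design is
#'   given).
#' @param n_pairs number of read pairs to simulate.
#' @param read_len read length in bases (default 100, 2 x 100 bp protocol).
#' @param frag_len_mean,frag_len_sd fragment length distribution in bases
#'   (defaults 250 and 25; `frag_len_mean` must be >= `read_len`).
#' @param contaminant_refs named character vector of contaminant reference
#'   sequences (required when `contaminant_fraction > 0`; each at least
#'   `read_len` long).
#' @param contaminant_fraction fraction of pairs copied verbatim from the
#'   contaminant references (default 0).
#' @param adapter adapter sequence for read-through events.
#' @param readthrough_rate fraction of fragments with inserts shorter than
#'   the read length (default 0).
#' @param readthrough_insert mean insert length of read-through fragments in
#'   bases (default 50).
#' @param quality_profile `"decay"` (logistic drop from ~Q38 to ~Q10 over the
#'   final third of the read, exercising the adaptive trimmer) or `"flat40"`.
#' @param sample_id sample identifier recorded in the truth table.
#' @param seed RNG seed; identical arguments and seed give identical output.
#' @return list with elements `pairs` (a [pair_set]) and `truth` (data frame
#'   with one row per pair: `fragment_id`, `sample_id`, `origin_id`,
#'   `origin_type` in transcript/spike/contaminant, `insert_len`,
#'   `adapter_pos`, NA when no adapter was planted).
#' @export
simulate_reads <- function(transcripts, abundances, spike_design = NULL,
                           spike_sequences = NULL, n_pairs = 10000,
                           read_len = 100, frag_len_mean = 250,
                           frag_len_sd = 25, contaminant_refs = NULL,
                           contaminant_fraction = 0,
                           adapter = "AGATCGGAAGAGC", readthrough_rate = 0,
                           readthrough_insert = 50,
                           quality_profile = c("decay", "flat40"),
                           sample_id = "s0", seed = NULL) {
  quality_profile <- match.arg(quality_profile)
  stopifnot(frag_len_mean >= read_len,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            readthrough_rate >= 0, readthrough_rate <= 1)
  if (contaminant_fraction > 0) {
    if (is.null(contaminant_refs)) stop("contaminant_refs required")
    if (any(nchar(contaminant_refs) < read_len))
      stop("contaminant references must be at least read_len long")
  }
  if (is.null(names(transcripts)) || anyNA(match(names(transcripts),
                                                 names(abundances))))
    stop("abundances must be named and cover every transcript")
  local_seed(seed, {
    pool <- transcripts
    mpe <- unname(abundances[names(transcripts)])
    type <- rep("transcript", length(pool))
    if (!is.null(spike_design)) {
      if (is.null(spike_sequences))
        spike_sequences <- generate_spike_sequences(spike_design)
      spike_sequences <- spike_sequences[spike_design$spike_id]
      pool <- c(pool, spike_sequences)
      mpe <- c(mpe, spike_design$known_mpe)
      type <- c(type, rep("spike", nrow(spike_design)))
    }
    plens <- nchar(pool)
    n_contam <- rbinom(1L, n_pairs, contaminant_fraction)
    n_main <- n_pairs - n_contam

    sim_main <- function(n) {
      if (n == 0L) return(empty_sim())
      oi <- sample.int(length(pool), n, replace = TRUE, prob = mpe * plens)
      tlen <- plens[oi]
      rt <- runif(n) < readthrough_rate
      flen <- pmin(tlen, pmax(read_len,
                              round(rnorm(n, frag_len_mean, frag_len_sd))))
      ins <- rep(NA_integer_, n)
      if (any(rt)) {
        ins[rt] <- pmin(pmin(read_len - 1L, tlen[rt]),
                        pmax(15L, round(rnorm(sum(rt), readthrough_insert, 5))))
        flen[rt] <- ins[rt]
      }
      start <- 1L + floor(runif(n) * (tlen - flen + 1))
      end <- start + flen - 1L
      rl <- pmin(read_len, flen)
      s1 <- substring(pool[oi], start, start + rl - 1L)
      s2 <- revcomp(substring(pool[oi], end - rl + 1L, end))
      apos <- rep(NA_integer_, n)
      if (any(rt)) {
        fill1 <- embed_adapter(s1[rt], adapter, read_len)
        fill2 <- embed_adapter(s2[rt], adapter, read_len)
        s1[rt] <- fill1
        s2[rt] <- fill2
        apos[rt] <- ins[rt] + 1L
      }
      list(origin_id = names(pool)[oi], origin_type = type[oi],
           insert_len = ifelse(rt, ins, flen), adapter_pos = apos,
           s1 = s1, s2 = s2)
    }
    sim_contam <- function(n) {
      if (n == 0L) return(empty_sim())
      oi <- sample.int(length(contaminant_refs), n, replace = TRUE)
      tlen <- nchar(contaminant_refs)[oi]
      flen <- pmin(tlen, pmax(read_len,
                              round(rnorm(n, frag_len_mean, frag_len_sd))))
      start <- 1L + floor(runif(n) * (tlen - flen + 1))
      end <- start + flen - 1L
      s1 <- substring(contaminant_refs[oi], start, start + read_len - 1L)
      s2 <- revcomp(substring(contaminant_refs[oi], end - read_len + 1L, end))
      list(origin_id = names(contaminant_refs)[oi],
           origin_type = rep("contaminant", n),
           insert_len = flen, adapter_pos = rep(NA_integer_, n),
           s1 = s1, s2 = s2)
    }

    parts <- list(sim_main(n_main), sim_contam(n_contam))
    sim <- lapply(stats::setNames(nm = names(parts[[1]])), function(f)
      c(parts[[1]][[f]], parts[[2]][[f]]))
    ord <- sample.int(n_pairs)
    sim <- lapply(sim, `[`, ord)

    frag <- sprintf("frag%07d", seq_len(n_pairs))
    q1 <- quality_strings(nchar(sim$s1), quality_profile)
    q2 <- quality_strings(nchar(sim$s2), quality_profile)
    pairs <- pair_set(frag,
                      new_read_set(paste0(frag, "/1"), sim$s1, q1, 1L),
                      new_read_set(paste0(frag, "/2"), sim$s2, q2, 2L))
    truth <- data.frame(fragment_id = frag, sample_id = sample_id,
                        origin_id = sim$origin_id,
                        origin_type = sim$origin_type,
                        insert_len = sim$insert_len,
                        adapter_pos = sim$adapter_pos)
    list(pairs = pairs, truth = truth)
  })
}

empty_sim <- function() {
  list(origin_id = character(), origin_type = character(),
       insert_len = integer(), adapter_pos = integer(),
       s1 = character(), s2 = character())
}

# insert + adapter + random fill, truncated to read_len
embed_adapter <- function(inserts, adapter, read_len) {
  out <- substr(paste0(inserts, adapter), 1L, read_len)
  short <- nchar(out) < read_len
  if (any(short))
    out[short] <- paste0(out[short],
                         random_dna(read_len - nchar(out[short])))
  out
}

# positionwise quality profiles; "decay" drops logistically from ~Q38 to
# ~Q10 over the final third of the read, plus small integer jitter
quality_strings <- function(lens, profile) {
  if (profile == "flat40") return(strrep(rawToChar(as.raw(40L + 33L)), lens))
  vapply(lens, function(n) {
    if (n == 0L) return("")
    i <- seq_len(n)
    base <- 10 + 28 / (1 + exp((i - 5 * n / 6) / (n / 30)))
    q <- pmin(40L, pmax(2L, as.integer(round(base + rnorm(n, 0, 1.5)))))
    intToUtf8(q + 33L)
  }, character(1))
}

#' Simulate an alignment table from read truth
#'
#' Stands in for the aligner: every surviving non-contaminant fragment gets
#' one record to its true transcript; a `multimap_rate` share additionally
#' hits one random decoy transcript, and a `discordant_rate` share is
#' flagged `concordant = FALSE`.
#'
#' @param truth truth data frame from [simulate_reads()].
#' @param multimap_rate fraction of fragments with one extra decoy record
#'   (default 0).
#' @param discordant_rate fraction of fragments flagged discordant
#'   (default 0).
#' @param decoy_pool transcript IDs decoys are drawn from, uniformly. By
#'   default (`NULL`) decoys are instead drawn from the empirical fragment
#'   distribution of `truth`, emulating multi-mapping between co-expressed
#'   homologs: the extra-hit load on a transcript stays proportional to its
#'   expression rather than spreading a uniform cross-contamination floor
#'   over rare transcripts.
#' @param surviving_fragments optional fragment IDs that survived QC as
#'   pairs; others produce no record.
#' @param seed RNG seed.
#' @return alignment data frame (`fragment_id`, `transcript_id`,
#'   `concordant`, `sample_id`).
#' @export
simulate_alignments <- function(truth, multimap_rate = 0, discordant_rate = 0,
                                decoy_pool = NULL, surviving_fragments = NULL,
                                seed = NULL) {
  stopifnot(multimap_rate >= 0, multimap_rate <= 1,
            discordant_rate >= 0, discordant_rate <= 1)
  rows <- truth[truth$origin_type != "contaminant", , drop = FALSE]
  if (!is.null(surviving_fragments))
    rows <- rows[rows$fragment_id %in% surviving_fragments, , drop = FALSE]
  all_ids <- unique(truth$origin_id[truth$origin_type != "contaminant"])
  local_seed(seed, {
    n <- nrow(rows)
    conc <- runif(n) >= discordant_rate
    out <- data.frame(fragment_id = rows$fragment_id,
                      transcript_id = rows$origin_id,
                      concordant = conc, sample_id = rows$sample_id)
    mm <- which(runif(n) < multimap_rate)
    if (length(mm) && length(all_ids) > 1L) {
      draw <- function(k) {
        if (is.null(decoy_pool)) rows$origin_id[sample.int(n, k,
                                                           replace = TRUE)]
        else decoy_pool[sample.int(length(decoy_pool), k, replace = TRUE)]
      }
      decoy <- draw(length(mm))
      clash <- decoy == rows$origin_id[mm]
      tries <- 0L
      while (any(clash) && tries < 20L) {
        decoy[clash] <- draw(sum(clash))
        clash <- decoy == rows$origin_id[mm]
        tries <- tries + 1L
      }
      if (any(clash)) {  # dominant-origin fragments: fall back to uniform
        decoy[clash] <- vapply(rows$origin_id[mm][clash], function(o)
          sample(setdiff(all_ids, o), 1L), character(1))
      }
      out <- rbind(out, data.frame(fragment_id = rows$fragment_id[mm],
                                   transcript_id = decoy,
                                   concordant = conc[mm],
                                   sample_id = rows$sample_id[mm]))
    }
    rownames(out) <- NULL
    out
  })
}
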