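---
title: "Quantitative de novo transcriptomics: QC, spike-in calibration and transcript families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative de novo transcriptomics: QC, spike-in calibration and transcript families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`denovoquant` reimplements the quantitative scaffolding around a de novo
transcriptome assembly of a non-model organism: everything a study needs
before and after the assembler itself. The assembler (Trinity, Velvet/Oases,
...) is treated as an external black box; this package covers read quality
control, absolute quantification through ERCC-style spike-ins, and
homology-based transcript-family analysis. This vignette records the models,
the tunable parameters, and the design decisions that were genuinely open.

```{r load}
library(denovoquant)
```

## The two-phase quality-control cascade

Raw paired-end libraries (2 x 100 bp, directional) carry several artifact
classes that would otherwise propagate into the assembly: leftover adapter
from short inserts, overabundant rRNA/mtRNA fragments, low-complexity
technical reads, a GC-composition bias over the first bases caused by
random-hexamer priming, and declining 3' base quality. The cascade treats
these in a fixed order, phase 1 at the fragment level and phase 2 at the
read level:

1. **Adapter clipping.** For each read the clipper finds the leftmost
   position where a prefix of the adapter matches the read suffix with
   overlap >= `min_adapter_overlap` (default 5 bases) and a mismatch
   fraction <= `max_adapter_mismatch_rate` (default 0.1); a full internal
   adapter occurrence also truncates at its start. These two knobs trade
   sensitivity on short read-through inserts against random clipping (at
   the defaults, a random 5-base suffix match occurs in roughly 0.1% of
   reads and costs only those few terminal bases).
2. **Contaminant screening.** Reads are screened against a catalog of
   rRNA/mtRNA reference sequences with a canonical k-mer index
   (`contaminant_k = 25`): a read matching at least `min_shared_kmers`
   (default 1) indexed 25-mers — on either strand, since canonical k-mers
   are strand-agnostic — marks its whole pair as contaminant. Removing the
   pair, not the read, reflects that a contaminant fragment contaminates
   both mates. The filter is alignment-free by design so the package has no
   external aligner dependency; its guarantees are characterised in the
   test suite rather than assumed: verbatim copies of indexed references of
   length >= k can never be missed (every window is indexed), while the
   false-positive rate against a 10-kb catalog is bounded by the ~4^-25
   chance of a random 25-mer collision.
3. **Low-complexity removal.** A read whose sequence contains at most two
   distinct informative bases is removed; `N` is ignored, so an all-`N`
   read is low complexity (and so is a read emptied by clipping).
4. **Prefix trimming.** The first `prefix_trim = 13` bases of every read
   are removed to cut the positional GC bias of random-hexamer priming.
   The trim is applied to both mates; it is positional from the original
   read start, which is why it runs before (and does not commute with) the
   adaptive 3' trim.
5. **Adaptive 3' trimming.** A `window = 5`-base window slides from the
   read end toward the start; while the window mean quality is below
   `min_mean_quality = 30` the final base is dropped and the window shifts
   by one. The original description leaves the end-game ambiguous once
   fewer than `window` bases remain; here the mean test is applied once to
   all remaining bases, removing them all if it fails, so that short
   uniformly-bad stubs cannot survive. The operation always returns a
   prefix of its input and is idempotent.
6. **Length filtering.** Reads shorter than `min_length = 25` bases are
   removed: reads shorter than the assembler's k-mer contribute nothing to
   assembly. The default matches a typical assembler k; it is configurable
   per target assembler.

A pair whose mates both survive stays paired; if exactly one mate is
removed the survivor becomes an *orphan* and is emitted separately. The
attrition report tallies pairs, orphans, reads and bases per stage, and the
identities `reads_in = reads_out + reads_removed` and
`reads_out = 2 * pairs_out + orphans_out` hold at every stage by
construction — the test suite checks them on every synthetic run.

## Fragment counting and FPKM

Quantification consumes a minimal alignment table (fragment, transcript,
concordant flag, sample); a SAM adapter is provided that reduces aligner
output to this table by mapping flag bit `0x2` to concordance. Only
concordant pairs are counted by default, matching a directional protocol.
Counting is per fragment, not per mate, and a fragment aligned to $m$
transcripts contributes $1/m$ to each:

$$\mathrm{FPKM}_{t,s} = \frac{c_{t,s}}{(L_t/10^3)\,(N_s/10^6)}$$

with $c_{t,s}$ the (possibly fractional) fragment count, $L_t$ the
transcript length in bases and $N_s$ the total counted fragments in the
sample. Uniform $1/m$ splitting is a deliberate simplification (an EM
re-assignment in the style of RSEM is out of scope): it keeps conservation
exact — per-sample counts sum to the number of counted fragments — at the
cost of blurring counts across close paralogs. Totals include spike-in
fragments, matching the "per million fragments mapped" denominator.
Transcript length is the full sequence length; no effective-length
correction is applied by default.

## Spike-in calibration to molecules per embryo

A known dose of synthetic spike-in RNA per embryo turns relative FPKM into
absolute molecules per embryo (MPE). For each sample the standard curve
regresses known spike-in MPE ($y$) on measured spike-in FPKM ($x$), both
log10-transformed:

$$\log_{10} \mathrm{MPE} = a + b \, \log_{10} \mathrm{FPKM}$$

Decisions worth recording:

* **log10 scale by default.** A 92-point design spanning six orders of
  magnitude would be dominated by its top points on a linear scale; the
  log-log fit weights the decades evenly. A linear-scale option is kept.
  Spike-ins with zero FPKM are excluded before the transform and
  `n_points` records what was actually used; fewer than three usable
  points is an error.
* **Orientation.** Known concentration is the response, FPKM the
  predictor, so inverse prediction needs no algebraic inversion:
  `predict_mpe()` maps FPKM 0 to MPE 0 and otherwise evaluates
  $10^{a + b\log_{10}\mathrm{FPKM}}$ (linear scale: clipped at zero). The
  map is monotone whenever $b > 0$.
* **Robust fitting.** The default fit is Huber IRLS with tuning constant
  $c = 1.345$ (95% efficiency at the Gaussian), scale re-estimated each
  iteration as the median absolute deviation of residuals divided by
  0.6745, an OLS start, a 50-iteration cap and a coefficient tolerance of
  1e-8; non-convergence is flagged, and `max_iter = 0` returns the flagged
  OLS start. Near the detection limit, spike-ins observed at one or two
  fragments sit above the dose-response line (only upward fluctuations are
  detected), and the robust loss reduces their leverage relative to OLS;
  with gross outliers it is strictly better, which the test suite checks
  against ordinary least squares and an independent M-estimator
  implementation (MASS). The OLS fit is exposed both for comparison and
  because its $R^2$ is the conventional curve-quality summary.

`count_expressed()` applies strict thresholds (MPE strictly above 0, or
100, in at least one sample), mirroring how expressed-transcript tallies
are reported per timepoint.

## Transcript families

BLASTx hits of transcripts against a protein database are filtered with
strict inequalities — e-value `< 5e-5` *and* percent identity `> 80` —
so hits exactly at a threshold are excluded. Qualifying hits induce a
bipartite transcript-subject graph; two transcripts sharing at least one
subject are linked, and families are the connected components of the
transitive closure (single linkage). Since queries were nucleotide
transcripts and subjects proteins, sharing a *subject* is the only linkage
the data supports; both linked transcripts' hits must themselves qualify.
Transcripts with no qualifying hit form no family. Family identifiers are
the lexicographically smallest member, making output reproducible and
independent of hit order (the suite verifies equality with a brute-force
pairwise-closure oracle and invariance under permutation).

Family-level quantities follow: summed member MPE per sample, and the
percent of the genome transcribed above a threshold — the summed length of
each qualifying family's longest member divided by the genome length
(450 Mbp by default, a sea-anemone-scale genome). Assembly statistics use
the weighted-median N50 convention: the largest length $L$ such that
transcripts of length $\ge L$ cover at least half the assembly.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth, so the whole chain is testable without any download:

* **Transcripts** have log-normal lengths (mean 600 bp, `sdlog = 0.7`,
  floor 100 bp) — the short-read de novo regime with a tail past 1 kb.
* **Spike-in designs** are log-even grids, 92 points over 6 decades by
  default.
* **Reads**: fragments are drawn with probability proportional to
  abundance x length — the standard RNA-seq sampling model implicitly
  assumed by FPKM — so per-transcript counts are multinomial at fixed
  library size (Poisson conditioned on depth), making count conservation
  exact. Mates read from opposite fragment ends, mate 2
  reverse-complemented (directional protocol). Planted, truth-recorded
  failure modes: verbatim contaminant pairs; adapter read-through
  (fragments shorter than the read embed the adapter at a recorded
  position in both mates); and a 3' quality decay modelled as a logistic
  drop from ~Q38 to ~Q10 over the final third of the read — arbitrary but
  configurable, chosen to exercise the adaptive trimmer non-trivially.
* **Alignments**: each surviving fragment maps to its true transcript; a
  configurable share is flagged discordant, and a multi-mapping share
  gains one decoy record. Decoys are drawn from the library's empirical
  fragment distribution rather than uniformly over transcripts: real
  multi-mapping links co-expressed homologs, and a uniform decoy floor
  would deposit constant phantom counts on rare transcripts and visibly
  bend the bottom of the standard curve.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: per-cycle substitution/indel error profiles,
coverage unevenness along transcripts, true paralog sequence similarity
(multi-mapping is injected by label, not by sequence), library-prep GC
bias beyond the trimmed prefix, and assembly fragmentation itself.

```{r example}
tx <- generate_transcripts(30, seed = 1)
design <- generate_spikein_design(92, 6)
truth <- generate_expression_truth(names(tx), "t0", 1, 4.5, seed = 2)
sim <- simulate_reads(tx, truth[, 1], design, n_pairs = 5000, seed = 3)
res <- apply_qc_pipeline(sim$pairs, qc_config())
qc_phase_summary(res$report)
```

## Numerical choices and degenerate inputs

* Qualities are Phred scores in [0, 93]; +33 is the default file encoding
  (HiSeq-era data), +64 available. Internally everything is held +33.
* Mate identity is derived by stripping a trailing `/1`/`/2`, then
  anything after the first whitespace — a convention, since read-naming
  schemes vary.
* Window means compare against the threshold with a 1e-9 slack so integer
  quality sums never fail an exact-boundary test to floating-point noise.
* `N` never matches in adapter comparison or k-mer indexing (windows
  containing `N` are skipped); ties for a family's longest member are
  irrelevant to the genome fraction (length is what is summed).
* Degenerate regressors (all-equal x), empty length lists, all-zero
  spike-ins, and totals of zero mapped fragments are hard errors, not
  silent results.

## Problem sizes used by the test suite

The archived study-scale dataset (~24 Gbases) is not reproducible at desk
scale, so the suite establishes properties on generated data: trimmer and
assembly-statistics oracles on 10,000 reads / 1,000 length lists,
conservation on a 100,000-pair run, contaminant screening on 10,000-pair
simulations, calibration recovery on the full 92-point design across 50
seeds, end-to-end MPE recovery on 20 seeds of 40,000-pair libraries, and
family clustering against a brute-force oracle on 1,000 random instances.
These sizes were chosen so the full suite runs in minutes on one CPU while
every asserted property is exercised far from trivially.

## Known limitations

Uniform multi-map splitting biases counts toward popular paralogs; the
contaminant screen inherits k-mer exact-matching's blindness to diverged
contaminants (below ~96% identity a 25-mer match is no longer guaranteed);
spike-in calibration assumes spike-ins experience the same capture
efficiency as endogenous mRNA; and near the detection limit predicted MPE
is upward-censored, so expressed-transcript counts just above a low
threshold should be read as detection counts, not abundance counts.
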