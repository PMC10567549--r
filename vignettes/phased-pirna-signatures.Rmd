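---
title: "Detecting phased piRNA biogenesis signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phased piRNA biogenesis signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnaphase)
```

## The biological problem and the model

In *Drosophila* testes, a Y-linked tandem-repeat locus produces piRNAs that
silence a selfish X-linked gene to which its repeats are ~90% identical.
Because the Y chromosome is absent from mothers, these piRNAs cannot be
deposited maternally; instead, maternally inherited piRNAs derived from a
DNA transposon whose insertion forms the 5' leader of the locus precursor
are thought to act as *triggers*: a trigger piRNA directs PIWI-catalysed
slicing of the precursor between target nucleotides t10 and t11 (the bases
paired to guide nucleotides g10 and g11), creating a long
5'-monophosphorylated *pre-pre-piRNA*. The mitochondrial endonuclease Zuc
then fragments this RNA 5'-to-3' into head-to-tail pre-piRNAs of ~26 nt,
most beginning with uridine (the 1U bias). The package implements the
sequence-level statistics that diagnose each step of this model, and a
generative simulator of the model itself, so that every statistic can be
verified end to end on data with known truth.

Three signatures carry the evidence:

1. **Slicing geometry.** For a plus-strand 5' end at position $P$ and a
   minus-strand 5' end at $G$ (0-based, with the minus-strand 5' end at the
   right edge of its footprint), the 5'-5' overlap is $o = G - P + 1$ nt.
   Guide-directed slicing places the product 5' end at exactly $o = 10$.
   `overlap_spectrum()` tabulates $o \in [0, 20]$ between pre-pre-piRNA 5'
   ends and candidate trigger piRNAs; `z_score()` computes
   $Z_{10} = (c_{10} - \bar{c}_{bg}) / \sigma_{bg}$, where the background
   is every displayed offset except 10, and a two-sided normal tail
   probability.
2. **Phasing periodicity.** `phasing_metaplot()` profiles piRNA 5'-end
   density downstream of each pre-pre-piRNA 5' end; `autocorrelate()` and
   `estimate_period()` read the ~25-26-nt period off the median profile.
3. **Composition biases.** `nt_composition()` quantifies the 1U bias of
   phased piRNAs (and the 10A bias diagnostic of ping-pong responders)
   against a background pooled over all positions of all species.

## Statistical and numerical choices

* **Population standard deviation** for the $Z_{10}$ background (20
  values): deterministic, scale-invariant ($Z$ is unchanged when every
  count is multiplied by $k > 0$), and well-defined without a sampling
  model. The sample-s.d. alternative would only rescale $Z$ by a constant
  $\sqrt{20/19}$.
* **Degenerate backgrounds.** A perfectly uniform spectrum returns $z = 0$,
  $p = 1$; a zero-variance background with a deviating focus raises a
  `degenerate_background` error rather than returning an infinity.
* **Weighting.** Spectra and metaplots default to read-count weighting
  (pair weight = product of read counts); species weighting (each distinct
  5' end counts once) is one flag away, because "frequency" in published
  displays is ambiguous between the two.
* **Permutation aggregation.** With replicate libraries, a spectrum is
  computed for every (small RNA dataset x long RNA dataset) permutation;
  `permutation_z()` reports both the mean of per-permutation $z$ values and
  the $z$ of the pooled spectrum, since either may be the displayed
  statistic.
* **Metaplot normalization.** Each pre-pre-piRNA's density vector is
  normalized to unit sum before averaging, so one abundant species cannot
  dominate the profile. The median and IQR across permutations summarize
  replicate structure.
* **Autocorrelation** is Pearson correlation on overlapping (non-circular)
  windows, lags 1-50 by default; profiles are short and aperiodic at their
  edges, where FFT-based circular estimates would wrap artefacts.
  Zero-variance windows give `NA`, never 0.
* **Harmonic ambiguity.** `estimate_period()` searches lags 15-40 and
  returns the maximum (ties toward the smaller lag). If an integer divisor
  of the peak below the search range carries comparable correlation
  (>= 0.8 of the peak), the result is flagged and warned about rather than
  silently resolved.
* **Junction window.** A pre-pre-piRNA call requires a >= 200-nt species
  (mirroring the library's size selection) on the precursor strand whose
  footprint crosses the insertion/locus-body junction and whose 5' end
  lies within +/- 100 nt of that junction. Centring reconciles "the 100 nt
  flanking the insertion" with "the last 100 nt of the insertion"; both the
  window and its centring are arguments.
* **Exact Mann-Whitney.** Published group sizes for long-RNA abundance
  comparisons are 2-3 libraries, where only an exact test is meaningful and
  ties are common after normalization. `rank_sum_test()` enumerates all
  $\binom{n_1+n_2}{n_1}$ arrangements with mid-ranks for groups up to 8,
  and falls back to the normal approximation above that.
* **Error propagation.** $\Delta C_t$ and $\Delta\Delta C_t$ standard
  deviations combine as $\sigma_x = \sqrt{\sigma_y^2 + \sigma_z^2}$; the
  fold change is $2^{-\Delta\Delta C_t}$ with a $\pm\sigma$ fold interval.

## Read processing

Small RNA libraries embed two 9-nt UMIs in fixed spacer triplets
(`NNN CGA NNN TCA NNN` or `NNN ATC NNN AGT NNN` at the 5' end; `NNN GTC NNN
TAG NNN` before the constant 3' adapter `TGGAATTCTCGGGTGCCAAGG`).
`parse_small_rna_reads()` validates the six spacers allowing one mismatch
in total -- strict matching would discard roughly 1-2% of genuine reads at
typical quality -- and reports structured rejection codes. PCR duplicates
collapse on the `(insert, umi5, umi3)` triple *before* mapping, matching
the processing order of the protocol; the count of a species is the number
of distinct UMI pairs that carried it. Spike-in classification is exact
(zero mismatches); rRNA classification allows one mismatch on either
strand. Long RNA reads carry only the 15-nt degenerate block, which
`strip_degenerate_block()` removes; reads sharing a genomic 5' end merge
into one species (`merge_long_rnas()`).

The desk-scale aligner (`align_ungapped()`) reports **all** positions on
both strands with at most `max_mm` mismatches (an `N` matches nothing), and
only when a sequence has no full-length hit does it split off a
non-templated 3' tail (<= 4 nt, matched prefix >= 18 nt), emulating how
tailed small RNAs are rescued. The inner scan is a compiled exhaustive
loop, so its behavior is definable in one sentence and testable against a
byte-by-byte oracle; genome-scale indexing is explicitly out of scope.
Multi-mappers default to fractional assignment (weight `count/n` over the
alignments of the best feature class), which conserves total read counts;
counting once per feature is available because both conventions exist in
the literature.

Spike-in calibration estimates reads-per-molecule as the **median** of the
six spike species' counts divided by the known molecules per species --
robust to a single failed ligation; the spiked molar amount and the total
RNA mass are configuration inputs.

## The simulator

`sim_config()` / `build_genome()` / `simulate_biogenesis()` /
`emit_reads()` generate: an X-like contig with a Ste-like gene; a Y-like
contig with a transposon insertion (5' leader) abutting a tandem array of
units mutated to 90% identity; autosomal genic control loci; rRNA and the
six printed spike-in oligos. Trigger piRNAs are drawn antisense to the
last 100 nt of the insertion; each sliced precursor molecule yields a
pre-pre-piRNA whose 5' end sits exactly 9 nt left of its trigger's 5' end
(the $o = 10$ geometry), followed by 5'-to-3' fragmentation.

Design choices that required judgement:

* **Fragment lengths and the 1U bias.** Spacings are drawn
  ~Normal(`phase_length_mean`, `phase_length_sd`) and rounded; each
  downstream cut is then displaced to the nearest uridine (with probability
  `u1_bias`) or the nearest non-uridine (otherwise), searching outward with
  a downstream tie preference. Displacements are typically <= 2 nt, so the
  period stays interpretable, and the measured position-1 U fraction equals
  `u1_bias` by construction, making composition recovery a meaningful test.
  Rejection sampling was rejected: it would distort the length
  distribution. With `phase_length_sd = 0` the grid is exact and base
  selection is disabled; with `u1_bias = 0` cuts are left where drawn (no
  base preference). These degenerate modes isolate geometry from
  composition for diagnostics.
* **The first fragment** of each chain keeps the slice-defined 5' end
  regardless of its base: the trigger, not Zuc, defines it. This dilutes
  the measured 1U fraction by under one percentage point at default sizes.
* **Deliberate simplifications.** Because every precursor molecule is
  fragmented independently, chains initiated at different slice sites do
  not share cut positions; real loci likely develop genomically reproducible
  cut sites, which *strengthens* periodicity in vivo. Consequently the
  package's period-recovery experiments use a single slicing site with
  `u1_bias = 0`, isolating pure phase geometry -- with 30 interleaved
  initiation sites inside a 90-nt window, cross-chain density dilutes the
  per-RNA periodic signal and the default-configuration period estimate is
  noticeably noisier. This is stated here so that a strong period estimate
  from the default pipeline is not over-interpreted.
* **Decay controls.** Genic loci shed long RNAs with uniformly random
  5' ends (sense) and small fragments on both strands; they provide the
  negative control for the slicing spectrum ($|z| \le 2$ expected) and are
  never constrained to the offset-10 geometry.
* **Responders.** Optional ping-pong responders start 10 nt offset from a
  phased guide and carry adenine at position 10 with probability
  `a10_bias`, implemented as a sequence edit (a non-templated signature the
  aligner's one-mismatch budget absorbs). The default responder pool is
  empty, matching the phasing-dominated locus being modelled.
* **Reads.** `emit_reads()` wraps each sampled molecule in the full
  adapter/UMI grammar with independent random UMIs and per-base
  substitution errors (default 0.1%), and emits long-RNA reads as
  5'-anchored sequences (up to 300 nt) behind the degenerate block. Long
  reads are emitted long enough to make the >= 200-nt size selection
  meaningful, a simplification relative to paired-end 79-nt reads whose
  extents would need inference.
* **Determinism.** All randomness flows from one seed through
  `derive_seed()` sub-streams, so genomes, truth tables and FASTQ files are
  byte-identical across runs.

What the simulator does **not** emulate: germline developmental timing,
chromatin or transcription dynamics, ligation and PCR sequence biases,
quality-score structure, multi-locus genome complexity, or
immunoprecipitation-resolved PIWI-protein partitioning. Passing tests
therefore demonstrate the correctness and statistical behavior of the
analysis code under the stated generative model, not performance on real
libraries.

## Problem sizes

The packaged experiments run at desk scale, chosen so the full suite and
the acceptance script each finish in minutes on one CPU: a ~20-kb genome
(six 400-nt repeat units, a 1-kb insertion, three 2-kb genic controls), 30
trigger species over ~3,000 molecules, 100 fragmented precursor molecules
(~10,000 phased piRNAs), two replicate libraries of 20,000 small RNA and
3,000 long RNA reads. Aligner correctness is verified against an
exhaustive oracle on 50-kb genomes with 200 reads. These sizes are
configuration, not limits; every generator parameter scales.

## Known limitations

* The aligner is exhaustive by design; do not point it at a real genome.
* Pre-pre-piRNA calling assumes a single annotated insertion/locus
  junction per call; loci with multiple insertions need one call per
  junction.
* The period estimator reports at most one peak; mixtures of two phased
  populations with different periods will surface only the stronger, with
  the harmonic flag as the sole hint.
* Exact rank-sum enumeration grows combinatorially; above 8 per group the
  normal approximation is used (with ties handled by mid-ranks).
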