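# pirnaphase

Signatures of phased piRNA biogenesis from small RNA and
5'-monophosphorylated long RNA (degradome) sequencing.

In fly testes, maternally inherited transposon piRNAs are thought to
*trigger* production of Y-linked piRNAs: a trigger piRNA directs slicing of
a precursor transcript between target nucleotides t10/t11, creating a long
5'-monophosphorylated pre-pre-piRNA that the endonuclease Zuc fragments
5'-to-3' into head-to-tail ~26-nt pre-piRNAs, most beginning with uridine.
`pirnaphase` is for small RNA bioinformaticians who want to test this class
of model in their own data: it implements the read processing, the
diagnostic statistics, and a truth-tagged simulator of the biogenesis model
so every stage can be verified without external data.

## What it computes

* **Slicing geometry.** For a plus-strand 5' end at `P` and a minus-strand
  5' end at `G` (0-based; a minus-strand 5' end is the right edge of its
  footprint), the 5'-5' overlap is `o = G − P + 1`. Guide-directed slicing
  puts the product 5' end at exactly `o = 10`. `overlap_spectrum()` counts
  offsets 0-20 and `z_score()` computes
  `Z10 = (c10 − mean(bg)) / sd(bg)` against the background of all displayed
  offsets except 10, with a two-sided normal `P`.
* **Phasing periodicity.** `phasing_metaplot()` profiles piRNA 5'-end
  density along pre-pre-piRNAs (per-RNA unit-sum normalization, median/IQR
  across dataset permutations); `autocorrelate()` + `estimate_period()`
  extract the ~25-26-nt period, flagging harmonic ambiguity.
* **Composition biases.** `nt_composition()` measures the 1U and 10A
  fractions against an all-position background.
* **Read processing.** Split-UMI adapter parsing
  (`parse_small_rna_reads()`), PCR-duplicate collapse (`deduplicate()`),
  rRNA/spike-in classification, a desk-scale exhaustive ungapped aligner
  with non-templated 3'-tail detection (`align_ungapped()`), long-RNA
  5'-end merging (`merge_long_rnas()`), and pre-pre-piRNA calling at an
  insertion/locus junction (`identify_prepre()`).
* **Quantification.** Spike-in calibrated absolute abundance
  (`absolute_abundance()`, molecules per 10 pg total RNA), exact
  Mann-Whitney abundance comparisons (`compare_abundance()`), and
  `2^-ddCt` with `sigma = sqrt(sigma_y^2 + sigma_z^2)` error propagation
  (`ddct()`).
* **Simulation.** `sim_config()`, `build_genome()`,
  `simulate_biogenesis()`, `emit_reads()`: a Su(Ste)-like tandem locus at
  90% identity to its target gene, an upstream transposon insertion,
  maternal triggers, t10/t11 slicing, phased fragmentation with a 1U bias,
  genic decay negatives, spike-ins, and full adapter/UMI read emission —
  with complete truth tables.

## Worked example

Simulate the default study (two replicate libraries each of 20,000 small
RNA and 3,000 long RNA reads) and run every stage:

```r
library(pirnaphase)
cfg <- sim_config(seed = 1)
report <- run_pipeline(cfg, "run")

report$signatures$z10_trigger    # 9.80
report$signatures$z10_genic      # 0.26
report$signatures$n_prepre       # 23 23
report$map$u1_percent            # 77.6
report$map$background_u_percent  # 25.7
report$abundance$trigger_pirna_per_10pg  # 3189
```

Reading the numbers: the 5' ends of called pre-pre-piRNA species (23 per
long-RNA library) overlap trigger piRNA 5' ends at offset 10 far in
excess of background (`Z10 = 9.8`, mean over the 2 x 2 library
permutations), while genic decay long RNAs show no such geometry
(`z = 0.26`). Locus piRNAs begin with uridine 77.6% of the time versus a
25.7% all-position background — the phased-biogenesis composition
signature. Spike-in calibration converts trigger piRNA reads to ~3,189
molecules per 10 pg total RNA against a configured truth of 3,000. The
`run/` directory holds the genome, annotation, FASTQ files, per-stage TSVs
(species tables, alignments, spectra, metaplot, autocorrelation) and
`report.json`.

Individual statistics work standalone, e.g. the analytic Z check:

```r
counts <- setNames(c(rep(1, 5), rep(3, 5), 12, rep(1, 5), rep(3, 5)), 0:20)
z_score(counts)$z   # exactly 10: focus 12 vs background mean 2, pop. sd 1
```

A thin command-line wrapper over `run_pipeline()` is provided at
`inst/scripts/pirna-pipeline.R` for YAML-configured runs.

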