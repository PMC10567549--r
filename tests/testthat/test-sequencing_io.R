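ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

make_read <- function(insert, umi5 = "AAAAAAAAA", umi3 = "CCCCCCCCC",
                      variant = "A") {
  sp <- if (variant == "A") c("CGA", "TCA") else c("ATC", "AGT")
  b5 <- paste0(substr(umi5, 1, 3), sp[1], substr(umi5, 4, 6), sp[2],
               substr(umi5, 7, 9))
  b3 <- paste0(substr(umi3, 1, 3), "GTC", substr(umi3, 4, 6), "TAG",
               substr(umi3, 7, 9))
  paste0(b5, insert, b3, ADAPTER)
}

test_that("split-UMI adapter grammar is parsed and validated", {
  insert <- "TGCTTGGACTACATATGGTTG"
  r <- paste0("AAACGAAAATCAAAA", insert, "CCCGTCCCCTAGCCC", ADAPTER)
  p <- parse_small_rna_reads(r)
  expect_equal(p$status, "ok")
  expect_equal(p$insert, insert)
  expect_equal(p$umi5, "AAAAAAAAA")
  expect_equal(p$umi3, "CCCCCCCCC")
  expect_equal(p$variant, "A")

  pB <- parse_small_rna_reads(make_read(insert, "GATTACAGA", "TTTGGGCCC",
                                        variant = "B"))
  expect_equal(pB$variant, "B")
  expect_equal(pB$umi5, "GATTACAGA")
  expect_equal(pB$umi3, "TTTGGGCCC")

  # no constant 3' adapter anywhere
  expect_equal(parse_small_rna_reads(strrep("ACGT", 20))$status, "no_adapter")

  # adapter directly after the two degenerate blocks: empty insert
  r_empty <- paste0("AAACGAAAATCAAAA", "CCCGTCCCCTAGCCC", ADAPTER)
  expect_equal(parse_small_rna_reads(r_empty)$status, "empty_insert")

  # one spacer mismatch tolerated, two rejected
  one_mm <- paste0("AAACGAAAATCAAAA", insert, "CCCGGCCCCTAGCCC", ADAPTER)
  expect_equal(parse_small_rna_reads(one_mm)$status, "ok")
  two_mm <- paste0("AAACGAAAATGAAAA", insert, "CCCGGCCCCTAGCCC", ADAPTER)
  expect_equal(parse_small_rna_reads(two_mm)$status, "bad_umi_structure")
})

test_that("deduplication collapses by insert + UMI pair, order-independently", {
  parsed <- data.frame(
    id = sprintf("r%d", 1:5),
    insert = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
               "ACGTACGTACGTACGTAC", "TTTTACGTACGTACGTAC",
               "TTTTACGTACGTACGTAC"),
    umi5 = c("AAAAAAAAA", "AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC",
             "CCCCCCCCC"),
    umi3 = c("GGGGGGGGG", "GGGGGGGGG", "TTTTTTTTT", "GGGGGGGGG",
             "GGGGGGGGG"),
    variant = "A", status = "ok", stringsAsFactors = FALSE
  )
  sp <- deduplicate(parsed)
  expect_equal(sp$count[sp$sequence == "ACGTACGTACGTACGTAC"], 2L)
  expect_equal(sp$count[sp$sequence == "TTTTACGTACGTACGTAC"], 1L)

  set.seed(42)
  for (i in 1:5) {
    expect_identical(deduplicate(parsed[sample(nrow(parsed)), ]), sp)
  }
  # feeding duplicated input changes nothing
  expect_identical(deduplicate(rbind(parsed, parsed)), sp)
})

test_that("classification separates spike-ins, rRNA and retained species", {
  rrna <- Biostrings::DNAStringSet(c(
    rRNA_2S = "TGCTTGGACTACATATGGTTGAGGGTTGTA",
    rRNA_X = rand_dna_chr(200)
  ))
  spikes <- Biostrings::DNAStringSet(c(spike1 = "TGCTAGTCTTATCGACCTCCTCATAG"))
  sp <- data.frame(
    sequence = c("TGCTAGTCTTATCGACCTCCTCATAG",         # printed spike-in 1
                 "TGCTTGGACTACATATGGTTGAGGGTTGTA",     # 2S, exact
                 "TGCTTGGACTACATATGCTTGAGGGTTGTA",     # 2S with 1 mismatch
                 "TACAACCCTCAACCATATGTAGTCC",          # 2S antisense fragment
                 "GATCGATCGATCGATCGATCGATCG"),         # unrelated
    count = c(5L, 4L, 3L, 2L, 1L)
  )
  out <- classify_reads(sp, rrna, spikes)
  expect_equal(out$class,
               c("spikein", "rrna", "rrna", "rrna", "retained"))
  expect_equal(out$spike_id[1], "spike1")

  # spike precedence over rRNA when a sequence is in both reference sets
  rrna2 <- c(rrna, spikes)
  expect_equal(classify_reads(sp, rrna2, spikes)$class[1], "spikein")
})

test_that("spike calibration converts read counts to absolute abundance", {
  cal <- spike_calibration(rep(10, 6), molecules_per_species = 1e6,
                           total_rna_pg = 100)
  expect_equal(absolute_abundance(5, cal), 5e4)
  expect_equal(absolute_abundance(0, cal), 0)
  expect_error(spike_calibration(rep(0, 6), 1e6, 100), class = "uncalibrated")

  # linear in the target count
  expect_equal(absolute_abundance(7 * 13, cal), 13 * absolute_abundance(7, cal))

  # invariant when every count (spikes and target) is scaled together
  cal3 <- spike_calibration(rep(10, 6) * 3L, 1e6, 100)
  expect_equal(absolute_abundance(5 * 3L, cal3), absolute_abundance(5, cal))

  # median makes the estimate robust to a single failed spike species
  cal_fail <- spike_calibration(c(0, 10, 10, 10, 10, 10), 1e6, 100)
  expect_equal(cal_fail$reads_per_molecule, 1e-5)
})

test_that("simulated reads round-trip: parse, dedup, classify recover truth", {
  cfg <- sim_config(seed = 21, sequencing_error_rate = 0,
                    depth_small = 2500L, depth_long = 200L,
                    precursor_molecules = 20L, trigger_molecules = 600L,
                    decay_small_species = 80L, decay_small_molecules = 300L,
                    decay_long_species = 40L, rrna_molecules = 300L,
                    spike_molecules = 150L, n_small_libs = 1L,
                    n_long_libs = 1L)
  gen <- build_genome(cfg)
  truth <- simulate_biogenesis(cfg, gen)
  reads <- emit_reads(truth, gen, cfg)
  lib <- reads$small_libs[[1]]

  parsed <- parse_small_rna_reads(lib$reads)
  expect_true(all(parsed$status == "ok"))
  expect_identical(parsed$insert, unname(lib$truth$sequence))

  species <- deduplicate(parsed)
  emitted <- tapply(rep(1L, nrow(lib$truth)), lib$truth$sequence, sum)
  expect_setequal(species$sequence, names(emitted))
  expect_equal(species$count,
               as.integer(emitted[species$sequence]),
               ignore_attr = TRUE)

  cls <- classify_reads(species, gen$rrna, gen$spikes)
  truth_class <- tapply(truth$small$class, truth$small$sequence,
                        function(x) x[1])
  expected <- c(trigger = "retained", phased = "retained",
                decay = "retained", rrna = "rrna", spikein = "spikein")
  got <- cls$class[match(names(truth_class)[names(truth_class) %in%
                                              cls$sequence], cls$sequence)]
  want <- expected[truth_class[names(truth_class) %in% cls$sequence]]
  expect_equal(got, unname(want))
})
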