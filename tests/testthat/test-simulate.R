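small_cfg <- function(seed = 41, ...) {
  base <- list(seed = seed, precursor_molecules = 20L,
               trigger_molecules = 500L, decay_small_species = 60L,
               decay_small_molecules = 200L, decay_long_species = 30L,
               decay_long_molecules = 60L, rrna_molecules = 200L,
               spike_molecules = 100L, depth_small = 1500L,
               depth_long = 300L, n_small_libs = 1L, n_long_libs = 1L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("genome construction is deterministic and honors identity", {
  cfg <- small_cfg()
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  # identity 1: repeat units equal the Ste-like sequence
  gi <- build_genome(small_cfg(identity_to_ste = 1))
  expect_true(all(gi$repeat_unit_sequences == gi$ste_sequence))

  # identity 0.9: per-unit Hamming distance within a binomial envelope
  g9 <- build_genome(small_cfg(identity_to_ste = 0.9))
  L <- nchar(g9$ste_sequence)
  hd <- vapply(g9$repeat_unit_sequences, function(u) {
    sum(strsplit(u, "")[[1]] != strsplit(g9$ste_sequence, "")[[1]])
  }, numeric(1))
  expect_true(all(abs(hd - 0.1 * L) <= 3 * sqrt(0.1 * 0.9 * L)))

  expect_error(build_genome(small_cfg(identity_to_ste = 0.3)),
               class = "bad_identity")

  # layout: the insertion abuts the locus body at the junction
  expect_equal(g1$layout$insertion$end, g1$layout$locus$start)
  expect_equal(g1$layout$junction, g1$layout$locus$start)
})

test_that("slicing obeys the t10/t11 geometry against its trigger", {
  cfg <- small_cfg()
  gen <- build_genome(cfg)
  truth <- simulate_biogenesis(cfg, gen)

  tr <- truth$triggers
  expect_true(all(tr$cut_site == tr$five_prime - 9L))
  expect_true(all(tr$cut_site >= truth$junction - 100L))
  expect_true(all(tr$cut_site < truth$junction))

  # every pre-pre-piRNA is called as a cleavage product of the trigger set
  pp <- truth$long[truth$long$class == "prepre", ]
  called <- call_cleavage_products(pp, tr)
  expect_equal(nrow(called), nrow(pp))

  # genic decay long RNAs are not constrained to the slicing geometry
  dl <- truth$long[truth$long$class == "decay_long", ]
  anti <- truth$small[truth$small$class == "decay" &
                        truth$small$strand == "-", ]
  frac <- nrow(call_cleavage_products(dl, anti)) / nrow(dl)
  expect_lt(frac, 0.2)

  # trigger sequences are genomic antisense of their footprint
  chrY <- as.character(gen$genome[["chrY"]])
  i <- which.max(tr$molecules)
  foot <- substr(chrY, tr$five_prime[i] - tr$length[i] + 2L,
                 tr$five_prime[i] + 1L)
  expect_equal(tr$sequence[i], rc_chr(foot))
})

test_that("phased fragmentation honors the 5'-U bias and degenerate modes", {
  # u1_bias = 1: every downstream fragment starts with U
  t1 <- simulate_biogenesis(small_cfg(u1_bias = 1))
  ph <- t1$small[t1$small$class == "phased", ]
  downstream <- !(ph$five_prime %in% t1$cut_sites)
  expect_true(all(substr(ph$sequence[downstream], 1, 1) == "T"))

  # sd = 0: exact grid, all fragment lengths equal the mean
  t0 <- simulate_biogenesis(small_cfg(phase_length_sd = 0))
  ph0 <- t0$small[t0$small$class == "phased", ]
  expect_true(all(ph0$length == 26L))

  # u1_bias = 0: no base selection, first-base U fraction near genomic T
  tu <- simulate_biogenesis(small_cfg(u1_bias = 0, precursor_molecules = 60L))
  phu <- tu$small[tu$small$class == "phased", ]
  fr <- weighted.mean(substr(phu$sequence, 1, 1) == "T", phu$molecules)
  expect_lt(abs(fr - 0.25), 0.08)
})

test_that("responders carry the configured 10A bias; XXY mode deposits piRNAs", {
  ta <- simulate_biogenesis(small_cfg(responder_species = 40L,
                                      responder_molecules = 200L,
                                      a10_bias = 1))
  rs <- ta$small[ta$small$class == "responder", ]
  expect_gt(nrow(rs), 0)
  expect_true(all(substr(rs$sequence, 10, 10) == "A"))

  t0 <- simulate_biogenesis(small_cfg(responder_species = 40L,
                                      responder_molecules = 200L,
                                      a10_bias = 0))
  rs0 <- t0$small[t0$small$class == "responder", ]
  expect_true(all(substr(rs0$sequence, 10, 10) != "A"))

  cfg <- small_cfg(xxy_mode = TRUE, deposit_species = 30L,
                   deposit_molecules = 100L)
  gen <- build_genome(cfg)
  tx <- simulate_biogenesis(cfg, gen)
  dep <- tx$small[tx$small$class == "deposited", ]
  expect_gt(nrow(dep), 0)
  expect_true(all(dep$five_prime >= gen$layout$locus$start &
                    dep$five_prime < gen$layout$locus$end))
})

test_that("read emission conserves counts and is reproducible", {
  cfg <- small_cfg(seed = 47)
  gen <- build_genome(cfg)
  truth <- simulate_biogenesis(cfg, gen)
  r1 <- emit_reads(truth, gen, cfg)
  r2 <- emit_reads(truth, gen, cfg)
  expect_identical(r1$small_libs[[1]]$reads, r2$small_libs[[1]]$reads)
  expect_identical(r1$long_libs[[1]]$reads, r2$long_libs[[1]]$reads)

  lib <- r1$small_libs[[1]]
  expect_equal(length(lib$reads), cfg$depth_small)
  # per-class emitted counts equal the multinomial draw recorded in truth
  expect_equal(sort(unique(lib$truth$class)),
               sort(unique(truth$small$class[lib$truth$species])))
  by_species <- table(lib$truth$species)
  expect_equal(sum(by_species), cfg$depth_small)

  # long reads are 5'-anchored: after the degenerate block they start with
  # the species 5' sequence (error-free reads)
  cfg0 <- small_cfg(seed = 48, sequencing_error_rate = 0)
  gen0 <- build_genome(cfg0)
  tr0 <- simulate_biogenesis(cfg0, gen0)
  rr <- emit_reads(tr0, gen0, cfg0)
  ll <- rr$long_libs[[1]]
  stripped <- strip_degenerate_block(ll$reads)
  sp <- tr0$long[ll$truth$species[1], ]
  chrom <- as.character(gen0$genome[[sp$chrom]])
  expect_equal(unname(substr(stripped[1], 1, 20)),
               substr(chrom, sp$five_prime + 1L, sp$five_prime + 20L))
})
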