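test_that("long RNA reads merge into 5'-end species", {
  aln <- data.frame(
    chrom = "c1", strand = "+",
    start = c(100L, 100L, 100L, 101L),
    end = c(310L, 350L, 400L, 420L)
  )
  sp <- merge_long_rnas(aln)
  expect_equal(nrow(sp), 2L)
  first <- sp[sp$five_prime == 100L, ]
  expect_equal(first$read_count, 3L)
  expect_equal(first$length, 300L)
  expect_equal(first$end, 400L)
  expect_equal(sp$read_count[sp$five_prime == 101L], 1L)

  # minus-strand 5' end is the right edge
  alnm <- data.frame(chrom = "c1", strand = "-", start = 50L, end = 300L)
  expect_equal(merge_long_rnas(alnm)$five_prime, 299L)
})

test_that("overlap spectrum matches hand enumeration and the all-pairs oracle", {
  a <- data.frame(chrom = "c", strand = "+", five_prime = 100L, count = 1L)
  b <- data.frame(chrom = "c", strand = "-",
                  five_prime = c(109L, 104L, 95L), count = 1L)
  sp <- overlap_spectrum(a, b)
  expect_equal(unname(sp$counts[c("10", "5")]), c(1, 1))
  expect_equal(sum(sp$counts), 2)  # the offset -4 pair is discarded

  empty <- overlap_spectrum(a, b[0, ])
  expect_true(all(empty$counts == 0))

  set.seed(13)
  for (i in 1:6) {
    x <- rand_end_set(25)
    y <- rand_end_set(20)
    for (wt in c("read", "species")) {
      expect_equal(overlap_spectrum(x, y, weighting = wt)$counts,
                   oracle_spectrum(x, y, weighting = wt))
    }
  }
})

test_that("Z10 is analytic on constructed spectra and scale-invariant", {
  counts <- stats::setNames(c(rep(1, 5), rep(3, 5), 12, rep(1, 5), rep(3, 5)),
                            0:20)
  z <- z_score(counts)
  expect_equal(z$z, 10)
  expect_equal(z$p, 2 * pnorm(-10))

  uni <- stats::setNames(rep(4, 21), 0:20)
  zu <- z_score(uni)
  expect_equal(zu$z, 0)
  expect_equal(zu$p, 1)

  # zero-variance background with a deviating focus is degenerate
  bad <- stats::setNames(c(rep(1, 10), 5, rep(1, 10)), 0:20)
  expect_error(z_score(bad), class = "degenerate_background")

  # invariant under multiplying every count by k > 0
  for (k in c(2, 0.5, 17)) {
    expect_equal(z_score(counts * k)$z, 10)
  }

  # permutation aggregation: mean of per-permutation z values
  s1 <- structure(list(counts = counts, focus = 10L, weighting = "read"),
                  class = "overlap_spectrum")
  s2 <- structure(list(counts = counts * 3, focus = 10L, weighting = "read"),
                  class = "overlap_spectrum")
  pz <- permutation_z(list(s1, s2))
  expect_equal(pz$z_mean, 10)
  expect_equal(pz$per_permutation, c(10, 10))
  expect_equal(pz$z_pooled, 10)
})

test_that("cleavage products require exact offset-10 guide geometry", {
  longs <- merge_long_rnas(data.frame(chrom = "c", strand = "+",
                                      start = 100L, end = 400L))
  g_hit <- data.frame(chrom = "c", strand = "-", five_prime = 109L)
  g_miss <- data.frame(chrom = "c", strand = "-", five_prime = 108L)
  expect_equal(nrow(call_cleavage_products(longs, g_hit)), 1L)
  expect_equal(nrow(call_cleavage_products(longs, g_miss)), 0L)
  expect_equal(nrow(call_cleavage_products(longs, g_hit[0, ])), 0L)

  # minus-strand product: guide 5' lies 9 nt upstream in genome coordinates
  lm <- merge_long_rnas(data.frame(chrom = "c", strand = "-",
                                   start = 100L, end = 400L))
  gm <- data.frame(chrom = "c", strand = "+", five_prime = 399L - 9L)
  expect_equal(nrow(call_cleavage_products(lm, gm)), 1L)
})

test_that("pre-pre-piRNAs are called at the insertion junction window", {
  locus <- list(chrom = "c", start = 1100L, end = 3000L, strand = "+",
                name = "locus")
  insertion <- list(chrom = "c", start = 900L, end = 1100L)
  mk <- function(fp, len) {
    merge_long_rnas(data.frame(chrom = "c", strand = "+",
                               start = fp, end = fp + len))
  }
  expect_equal(nrow(identify_prepre(mk(1050L, 400L), locus, insertion)), 1L)
  expect_equal(nrow(identify_prepre(mk(700L, 400L), locus, insertion)), 0L)
  expect_equal(nrow(identify_prepre(mk(1050L, 150L), locus, insertion)), 0L)
  # inside the window but not reaching the locus body
  expect_equal(nrow(identify_prepre(mk(1020L, 50L), locus, insertion,
                                    min_len = 40L)), 0L)
  expect_error(identify_prepre(mk(1050L, 400L), locus, NULL),
               class = "no_insertion")

  # monotone: shrinking the window or raising min_len never adds calls
  set.seed(17)
  longs <- merge_long_rnas(data.frame(
    chrom = "c", strand = "+",
    start = sample(800:1400, 60, replace = TRUE),
    end = sample(1500:3200, 60, replace = TRUE)
  ))
  base <- identify_prepre(longs, locus, insertion, window = 100L,
                          min_len = 200L)
  narrow <- identify_prepre(longs, locus, insertion, window = 40L,
                            min_len = 200L)
  strict <- identify_prepre(longs, locus, insertion, window = 100L,
                            min_len = 600L)
  key <- function(d) paste(d$chrom, d$five_prime, d$length)
  expect_true(all(key(narrow) %in% key(base)))
  expect_true(all(key(strict) %in% key(base)))
})

test_that("phasing metaplot normalizes per RNA and summarizes permutations", {
  prepre <- merge_long_rnas(data.frame(chrom = "c", strand = "+",
                                       start = 0L, end = 300L))
  pirnas <- data.frame(chrom = "c", strand = "+",
                       five_prime = c(0L, 26L, 52L), count = 1L)
  meta <- phasing_metaplot(prepre, pirnas, L = 60L)
  expect_equal(meta$median[c(1, 27, 53)], rep(1 / 3, 3))
  expect_equal(sum(meta$median), 1)

  # identical permutations give zero IQR
  meta2 <- phasing_metaplot(list(prepre, prepre), list(pirnas, pirnas),
                            L = 60L)
  expect_equal(nrow(meta2$profiles), 4L)
  expect_true(all(meta2$q75 - meta2$q25 == 0))

  # opposite-strand piRNAs never count
  anti <- transform(pirnas, strand = "-")
  expect_true(phasing_metaplot(prepre, anti, L = 60L)$all_zero)
})

test_that("autocorrelation matches the explicit-formula oracle", {
  set.seed(23)
  for (i in 1:5) {
    x <- runif(120)
    r <- autocorrelate(x, max_lag = 30L)
    for (lag in c(1L, 7L, 30L)) {
      expect_equal(unname(r[as.character(lag)]), oracle_autocorr(x, lag),
                   tolerance = 1e-9)
    }
  }
  expect_true(all(is.na(autocorrelate(rep(2, 100), max_lag = 20L))))
})

test_that("period estimation finds comb spacing and flags harmonics", {
  r26 <- autocorrelate(comb_profile(26L, 200L), max_lag = 50L)
  est <- estimate_period(r26)
  expect_equal(est$period, 26L)
  expect_false(est$harmonic)

  # comb of period 10 searched in [15, 40]: the 20-nt harmonic is reported
  # and flagged
  r10 <- autocorrelate(comb_profile(10L, 200L), max_lag = 50L)
  expect_warning(est10 <- estimate_period(r10), "harmonic")
  expect_equal(est10$period, 20L)
  expect_true(est10$harmonic)

  expect_error(estimate_period(autocorrelate(rep(1, 100), max_lag = 50L)),
               class = "no_period")
})
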