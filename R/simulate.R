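# Generative model of trigger-piRNA-initiated phased piRNA biogenesis.
#
# The simulated world: an X-like contig carrying a Ste-like gene; a Y-like
# contig carrying a tandem array of repeat units ~90% identical to the
# Ste-like sequence, with an upstream transposon insertion whose 3' part
# forms the 5' leader of the precursor transcript; an autosome-like contig
# with genic control loci; rRNA and spike-in reference records. Maternal
# trigger piRNAs antisense to the insertion slice the precursor between
# target nucleotides t10/t11, each slicing event creating a pre-pre-piRNA
# that is fragmented 5'-to-3' into head-to-tail pre-piRNAs with ~26-nt
# periodicity and a 5'-U bias. Genic loci shed uniform decay fragments as
# negatives. Every emitted molecule carries full truth provenance.

#' Configuration for the biogenesis simulator
#'
#' Defaults embody the modelled study conditions at desk scale: a tandem
#' locus at 90% identity to its target gene, a ~26 +/- 1 nt phase length,
#' a 77% 5'-U bias (matching the reported position-1 uridine fraction of
#' locus-derived piRNAs), 23-29-nt piRNAs, and two replicate libraries per
#' modality. All randomness derives from `seed` via per-stage sub-streams.
#'
#' @param seed Integer master seed.
#' @param repeat_units,repeat_unit_length Tandem array geometry.
#' @param identity_to_ste Per-base identity of each repeat unit to the
#'   Ste-like sequence (must be in (0.5, 1]).
#' @param insertion_length,leader_length Transposon insertion length and the
#'   part of it transcribed as the precursor 5' leader.
#' @param flank_length Neutral sequence around annotated elements.
#' @param trigger_pool_size,trigger_molecules Distinct maternal trigger
#'   piRNA species and their total molecule count.
#' @param precursor_molecules Precursor transcripts sliced and fragmented.
#' @param xxy_mode Also deposit mature locus-derived piRNAs directly
#'   (maternal deposition scenario).
#' @param deposit_species,deposit_molecules Deposited piRNA pool (xxy mode).
#' @param phase_length_mean,phase_length_sd Phase (fragment) length
#'   distribution in nt. With `phase_length_sd = 0` the cut grid is exact
#'   and composition snapping is disabled (diagnostic mode).
#' @param u1_bias Probability that a phased cut is placed on a uridine
#'   (otherwise on a non-uridine), so the measured position-1 U fraction of
#'   phased piRNAs equals `u1_bias`.
#' @param a10_bias Probability that a ping-pong responder carries adenine at
#'   position 10.
#' @param responder_species,responder_molecules Optional ping-pong responder
#'   pool (defaults 0: phasing-only, as seen for the modelled locus).
#' @param pirna_length_range Mature piRNA length range in nt.
#' @param n_genic_loci,genic_length Genic control loci.
#' @param decay_long_species,decay_long_molecules Uniform 5'-end decay
#'   species among long RNAs (negative controls).
#' @param decay_small_species,decay_small_molecules Genic small RNA decay
#'   fragments (both strands).
#' @param rrna_molecules Ribosomal RNA contamination molecules.
#' @param spike_molecules Molecules of each of the six spike-in oligos in
#'   the sample aliquot.
#' @param total_rna_pg Total RNA mass of the aliquot (pg).
#' @param depth_small,depth_long Sequenced reads per library.
#' @param long_read_length Emitted long-RNA read length cap (nt).
#' @param sequencing_error_rate Per-base substitution rate.
#' @param n_small_libs,n_long_libs Replicate libraries per modality.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       repeat_units = 6L, repeat_unit_length = 400L,
                       identity_to_ste = 0.90,
                       insertion_length = 1000L, leader_length = 300L,
                       flank_length = 300L,
                       trigger_pool_size = 30L, trigger_molecules = 3000L,
                       precursor_molecules = 100L,
                       xxy_mode = FALSE,
                       deposit_species = 100L, deposit_molecules = 2000L,
                       phase_length_mean = 26, phase_length_sd = 1,
                       u1_bias = 0.77, a10_bias = 0.35,
                       responder_species = 0L, responder_molecules = 0L,
                       pirna_length_range = c(23L, 29L),
                       n_genic_loci = 3L, genic_length = 2000L,
                       decay_long_species = 300L,
                       decay_long_molecules = 600L,
                       decay_small_species = 600L,
                       decay_small_molecules = 2000L,
                       rrna_molecules = 2000L,
                       spike_molecules = 1000L,
                       total_rna_pg = 10,
                       depth_small = 20000L, depth_long = 3000L,
                       long_read_length = 300L,
                       sequencing_error_rate = 0.001,
                       n_small_libs = 2L, n_long_libs = 2L) {
  cfg <- as.list(environment())
  for (p in c("u1_bias", "a10_bias", "sequencing_error_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("%s must be a probability in [0, 1]", p))
    }
  }
  stopifnot(cfg$leader_length <= cfg$insertion_length,
            cfg$phase_length_sd >= 0,
            cfg$pirna_length_range[1] <= cfg$pirna_length_range[2])
  structure(cfg, class = "sim_config")
}

# Printed spike-in oligos (DNA space) and the 2S rRNA sequence.
SPIKE_SEQUENCES <- c(
  spike1 = "TGCTAGTCTTATCGACCTCCTCATAG",
  spike2 = "TGCTAGTCTTCGATACCTCCTCATAG",
  spike3 = "TGCTAGTCTTGTCACGAACCTCATAG",
  spike4 = "TGCTAGTTATCGACCTTCATAG",
  spike5 = "TGCTAGTTCGATACCTTCATAG",
  spike6 = "TGCTAGTTGTCACGAATCATAG"
)
RRNA_2S <- "TGCTTGGACTACATATGGTTGAGGGTTGTA"

#' Build the simulated reference world
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_genome`: `genome` (DNAStringSet), feature
#'   `annotation`, `rrna` and `spikes` reference sets, and a `layout` list
#'   with the precursor, insertion, locus and gene intervals (0-based
#'   half-open) including the insertion/locus `junction`.
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$identity_to_ste <= 0.5 || cfg$identity_to_ste > 1) {
    stop_pp("bad_identity", "identity_to_ste must be in (0.5, 1]")
  }
  set.seed(derive_seed(cfg$seed, "genome"))
  fl <- cfg$flank_length

  ste <- random_dna(1, cfg$repeat_unit_length)
  units <- vapply(seq_len(cfg$repeat_units), function(i) {
    mutate_sequence(ste, 1 - cfg$identity_to_ste)
  }, character(1))
  insertion_seq <- random_dna(1, cfg$insertion_length)

  chrX <- paste0(random_dna(1, fl), ste, random_dna(1, fl))
  chrY <- paste0(random_dna(1, fl), insertion_seq,
                 paste(units, collapse = ""), random_dna(1, fl))
  gene_seqs <- random_dna(cfg$n_genic_loci, cfg$genic_length)
  chr2 <- paste0(random_dna(1, fl),
                 paste(vapply(gene_seqs, function(g) {
                   paste0(g, random_dna(1, fl))
                 }, character(1)), collapse = ""))

  ins_start <- fl
  ins_end <- fl + cfg$insertion_length
  rep_end <- ins_end + cfg$repeat_units * cfg$repeat_unit_length
  tss <- ins_end - cfg$leader_length

  genes <- lapply(seq_len(cfg$n_genic_loci), function(i) {
    s <- fl + (i - 1L) * (cfg$genic_length + fl)
    list(chrom = "chr2", start = s, end = s + cfg$genic_length,
         strand = "*", name = sprintf("gene%d", i))
  })

  annotation <- rbind(
    data.frame(chrom = "chrY", start = ins_start, end = ins_end,
               strand = "*", name = "hoppel_like", class = "insertion"),
    data.frame(chrom = "chrY", start = ins_end, end = rep_end,
               strand = "*", name = "suste_like", class = "pirna_locus"),
    data.frame(chrom = "chrX", start = fl,
               end = fl + cfg$repeat_unit_length,
               strand = "*", name = "ste_like", class = "genic"),
    do.call(rbind, lapply(genes, function(g) {
      data.frame(chrom = g$chrom, start = g$start, end = g$end,
                 strand = "*", name = g$name, class = "genic")
    }))
  )

  rrna <- Biostrings::DNAStringSet(c(rRNA_2S = RRNA_2S,
                                     rRNA_LSU = random_dna(1, 500)))
  structure(list(
    genome = Biostrings::DNAStringSet(c(chrX = chrX, chrY = chrY,
                                        chr2 = chr2)),
    annotation = annotation,
    rrna = rrna,
    spikes = Biostrings::DNAStringSet(SPIKE_SEQUENCES),
    ste_sequence = ste,
    repeat_unit_sequences = units,
    layout = list(
      junction = ins_end, tss = tss,
      precursor = list(chrom = "chrY", start = tss, end = rep_end,
                       strand = "+"),
      insertion = list(chrom = "chrY", start = ins_start, end = ins_end,
                       strand = "*", name = "hoppel_like"),
      locus = list(chrom = "chrY", start = ins_end, end = rep_end,
                   strand = "+", name = "suste_like"),
      ste = list(chrom = "chrX", start = fl,
                 end = fl + cfg$repeat_unit_length, strand = "-",
                 name = "ste_like"),
      genes = genes
    ),
    cfg = cfg
  ), class = "sim_genome")
}

#' Simulate the biogenesis model and produce truth tables
#'
#' Draws a pool of trigger piRNAs antisense to the insertion leader; each
#' sliced precursor molecule yields a pre-pre-piRNA whose 5' end obeys the
#' offset-10 geometry against its trigger (cut at plus-strand G - 9 for a
#' trigger 5' end at minus-strand G), and is then fragmented 5'-to-3' into
#' consecutive pre-piRNAs with lengths ~Normal(`phase_length_mean`,
#' `phase_length_sd`), each downstream cut placed on a uridine with
#' probability `u1_bias` (the slice-defined first fragment keeps its 5' end
#' unconditionally). Genic loci contribute uniform-decay long and small
#' species; spike-ins and rRNA complete the molecule pool.
#'
#' @param cfg A [sim_config()].
#' @param gen A [build_genome()] result (built from `cfg` if missing).
#' @return Object of class `sim_truth`: `small` and `long` species tables
#'   (class, sequence/coordinates, molecule counts), `triggers` (with their
#'   cut sites), `cut_sites`, `junction`, plus the generating `cfg` and a
#'   reference to `gen`.
#' @export
simulate_biogenesis <- function(cfg, gen = build_genome(cfg)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gen, "sim_genome"))
  set.seed(derive_seed(cfg$seed, "biogenesis"))
  chrY <- as.character(gen$genome[["chrY"]])
  chrY_chars <- strsplit(chrY, "", fixed = TRUE)[[1]]
  junction <- gen$layout$junction
  prec_end <- gen$layout$precursor$end
  lr <- cfg$pirna_length_range

  # --- maternal trigger piRNAs (antisense to the insertion leader) -------
  K <- cfg$trigger_pool_size
  cut_pool <- seq(junction - 100L, junction - 11L)
  if (length(cut_pool) < K) {
    stop_pp("insertion_too_short",
            "insertion leader cannot host the trigger pool")
  }
  cut_sites <- sort(sample(cut_pool, K))
  g5 <- cut_sites + 9L
  tlen <- sample(seq(lr[1], lr[2]), K, replace = TRUE)
  tseq <- revcomp(substr(rep(chrY, K), g5 - tlen + 2L, g5 + 1L))
  tmol <- as.vector(rmultinom(1, max(cfg$trigger_molecules - K, 0L),
                              prob = rexp(K))) + 1L
  triggers <- data.frame(
    class = "trigger", sequence = tseq, chrom = "chrY", strand = "-",
    five_prime = g5, length = tlen, molecules = tmol, cut_site = cut_sites,
    stringsAsFactors = FALSE
  )

  # --- slicing and 5'-to-3' phased fragmentation -------------------------
  frag_fp <- integer(0)
  frag_len <- integer(0)
  if (cfg$precursor_molecules > 0L) {
    sliced <- sample(K, cfg$precursor_molecules, replace = TRUE, prob = tmol)
    frags <- lapply(sliced, function(ti) {
      phase_chain(cut_sites[ti], prec_end, chrY_chars, cfg)
    })
    frag_fp <- unlist(lapply(frags, `[[`, "fp"))
    frag_len <- unlist(lapply(frags, `[[`, "len"))
  }
  phased <- aggregate_fragments(frag_fp, pmin(frag_len, lr[2]), chrY,
                                class = "phased")

  prepre <- data.frame()
  if (cfg$precursor_molecules > 0L) {
    ptab <- table(cut_sites[sliced])
    pfp <- as.integer(names(ptab))
    prepre <- data.frame(
      class = "prepre", chrom = "chrY", strand = "+", five_prime = pfp,
      length = prec_end - pfp, molecules = as.integer(ptab),
      stringsAsFactors = FALSE
    )
  }

  # --- optional ping-pong responders (antisense, 10A-biased) -------------
  responders <- data.frame()
  if (cfg$responder_species > 0L && nrow(phased) > 0L) {
    gi <- sample(nrow(phased), cfg$responder_species, replace = TRUE,
                 prob = phased$molecules)
    rg <- phased$five_prime[gi] + 9L
    rlen <- sample(seq(lr[1], lr[2]), cfg$responder_species, replace = TRUE)
    rseq <- revcomp(substr(rep(chrY, cfg$responder_species),
                           rg - rlen + 2L, rg + 1L))
    a10 <- runif(cfg$responder_species) < cfg$a10_bias
    substr(rseq[a10], 10, 10) <- "A"
    nonA <- !a10 & substr(rseq, 10, 10) == "A"
    substr(rseq[nonA], 10, 10) <- "C"
    rmol <- as.vector(rmultinom(
      1, max(cfg$responder_molecules - cfg$responder_species, 0L),
      prob = rep(1, cfg$responder_species))) + 1L
    responders <- data.frame(
      class = "responder", sequence = rseq, chrom = "chrY", strand = "-",
      five_prime = rg, length = rlen, molecules = rmol,
      stringsAsFactors = FALSE
    )
  }

  # --- maternally deposited mature piRNAs (XXY scenario) -----------------
  deposited <- data.frame()
  if (isTRUE(cfg$xxy_mode) && cfg$deposit_species > 0L) {
    dfp <- sample(seq(gen$layout$locus$start + 14L,
                      gen$layout$locus$end - lr[2] - 15L),
                  cfg$deposit_species, replace = TRUE)
    if (cfg$phase_length_sd > 0) {
      want_u <- runif(cfg$deposit_species) < cfg$u1_bias
      dfp <- vapply(seq_along(dfp), function(i) {
        snap_to_base(dfp[i], chrY_chars, want_u[i])
      }, integer(1))
    }
    dlen <- sample(seq(lr[1], lr[2]), cfg$deposit_species, replace = TRUE)
    dmol <- as.vector(rmultinom(
      1, max(cfg$deposit_molecules - cfg$deposit_species, 0L),
      prob = rep(1, cfg$deposit_species))) + 1L
    deposited <- data.frame(
      class = "deposited",
      sequence = substr(rep(chrY, cfg$deposit_species), dfp + 1L,
                        dfp + dlen),
      chrom = "chrY", strand = "+", five_prime = dfp, length = dlen,
      molecules = dmol, stringsAsFactors = FALSE
    )
  }

  # --- genic decay fragments (uniform 5' ends, both strands) -------------
  chr2 <- as.character(gen$genome[["chr2"]])
  genes <- gen$layout$genes
  ns <- cfg$decay_small_species
  gidx <- sample(length(genes), ns, replace = TRUE)
  dstrand <- sample(c("+", "-"), ns, replace = TRUE)
  dlen <- sample(18:35, ns, replace = TRUE)
  dstart <- vapply(seq_len(ns), function(i) {
    g <- genes[[gidx[i]]]
    sample(seq(g$start, g$end - dlen[i] - 1L), 1)
  }, integer(1))
  dseq_plus <- substr(rep(chr2, ns), dstart + 1L, dstart + dlen)
  dseq <- ifelse(dstrand == "+", dseq_plus, revcomp(dseq_plus))
  dmol <- as.vector(rmultinom(1, max(cfg$decay_small_molecules - ns, 0L),
                              prob = rep(1, ns))) + 1L
  decay_small <- data.frame(
    class = "decay", sequence = dseq, chrom = "chr2", strand = dstrand,
    five_prime = ifelse(dstrand == "+", dstart, dstart + dlen - 1L),
    length = dlen, molecules = dmol, stringsAsFactors = FALSE
  )

  nl <- cfg$decay_long_species
  lgidx <- sample(length(genes), nl, replace = TRUE)
  lstart <- vapply(seq_len(nl), function(i) {
    g <- genes[[lgidx[i]]]
    sample(seq(g$start, g$end - 200L), 1)
  }, integer(1))
  llen <- vapply(seq_len(nl), function(i) {
    g <- genes[[lgidx[i]]]
    min(sample(200:800, 1), g$end - lstart[i])
  }, integer(1))
  lmol <- as.vector(rmultinom(1, max(cfg$decay_long_molecules - nl, 0L),
                              prob = rep(1, nl))) + 1L
  decay_long <- data.frame(
    class = "decay_long", chrom = "chr2", strand = "+",
    five_prime = lstart, length = llen, molecules = lmol,
    stringsAsFactors = FALSE
  )

  # --- rRNA and spike-ins ------------------------------------------------
  lsu <- as.character(gen$rrna[["rRNA_LSU"]])
  rstart <- sample(seq_len(nchar(lsu) - 30L), 5)
  rlen <- sample(18:30, 5, replace = TRUE)
  rrna_seq <- c(RRNA_2S, substr(rep(lsu, 5), rstart, rstart + rlen - 1L))
  rmol <- c(round(cfg$rrna_molecules * 0.5),
            as.vector(rmultinom(1, cfg$rrna_molecules -
                                  round(cfg$rrna_molecules * 0.5),
                                prob = rep(1, 5))))
  rrna_df <- data.frame(
    class = "rrna", sequence = rrna_seq, chrom = NA_character_,
    strand = NA_character_, five_prime = NA_integer_,
    length = nchar(rrna_seq), molecules = rmol, stringsAsFactors = FALSE
  )
  spike_df <- data.frame(
    class = "spikein", sequence = unname(SPIKE_SEQUENCES),
    chrom = NA_character_, strand = NA_character_,
    five_prime = NA_integer_, length = nchar(SPIKE_SEQUENCES),
    molecules = cfg$spike_molecules, stringsAsFactors = FALSE
  )

  small_cols <- c("class", "sequence", "chrom", "strand", "five_prime",
                  "length", "molecules")
  small <- rbind(triggers[, small_cols], phased[, small_cols])
  for (extra in list(responders, deposited)) {
    if (nrow(extra)) small <- rbind(small, extra[, small_cols])
  }
  small <- rbind(small, decay_small[, small_cols], rrna_df[, small_cols],
                 spike_df[, small_cols])
  rownames(small) <- NULL
  long <- rbind(prepre, decay_long)
  rownames(long) <- NULL

  structure(list(
    small = small, long = long, triggers = triggers,
    cut_sites = cut_sites, junction = junction,
    cfg = cfg, layout = gen$layout
  ), class = "sim_truth")
}

# One precursor molecule's phased cut chain starting at the slice site.
#
# Downstream cut positions are drawn tail-to-head with spacings
# ~Normal(phase_length_mean, phase_length_sd), rounded. When a 5'-U bias is
# requested, each cut is then displaced to the nearest uridine (with
# probability u1_bias) or the nearest non-uridine (otherwise), searching
# outward with a downstream preference; the displacement is typically <= 2
# nt, so the phase geometry stays interpretable while the measured
# position-1 U fraction of phased piRNAs equals u1_bias. With
# phase_length_sd = 0 or u1_bias = 0 no base selection is applied (an exact
# cut grid / an unbiased chain), which isolates the geometry for
# diagnostics. The slice-defined first fragment keeps its 5' end
# unconditionally: the trigger, not the downstream endonuclease, defines it.
phase_chain <- function(p0, prec_end, chars, cfg) {
  est <- max(8L, ceiling((prec_end - p0) / max(cfg$phase_length_mean - 3, 1)))
  cuts <- integer(est)
  cuts[1] <- p0
  n <- 1L
  s <- p0
  snap <- cfg$phase_length_sd > 0 && cfg$u1_bias > 0
  repeat {
    len <- max(16L, as.integer(round(rnorm(1, cfg$phase_length_mean,
                                           cfg$phase_length_sd))))
    nxt <- s + len
    if (snap) {
      nxt <- snap_to_base(nxt, chars, runif(1) < cfg$u1_bias)
    }
    if (nxt > prec_end - 16L || nxt <= s) break
    n <- n + 1L
    if (n > length(cuts)) cuts <- c(cuts, integer(est))
    cuts[n] <- nxt
    s <- nxt
  }
  cuts <- cuts[seq_len(n)]
  if (n < 2L) return(list(fp = integer(0), len = integer(0)))
  fp <- cuts[-n]
  len <- diff(cuts)
  keep <- len >= 15L
  list(fp = fp[keep], len = len[keep])
}

# Nearest position whose base is (want_u) or is not (want_u = FALSE) a T,
# searching outward, downstream preferred on ties. The wide fallback bound
# keeps the want/got agreement essentially exact (the search practically
# never fails at 25% U content) while typical displacements stay within
# 2 nt.
snap_to_base <- function(pos, chars, want_u) {
  for (off in c(0L, as.integer(rbind(1:29, -(1:29))))) {
    p <- pos + off
    if (p < 0L || p >= length(chars)) next
    is_t <- chars[p + 1L] == "T"
    if (is_t == want_u) return(p)
  }
  pos
}

aggregate_fragments <- function(fp, len, chrom_seq, class) {
  if (length(fp) == 0L) {
    return(data.frame(class = character(0), sequence = character(0),
                      chrom = character(0), strand = character(0),
                      five_prime = integer(0), length = integer(0),
                      molecules = integer(0)))
  }
  key <- paste(fp, len)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  ufp <- as.integer(vapply(parts, `[`, character(1), 1))
  ulen <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(
    class = class,
    sequence = substr(rep(chrom_seq, length(ufp)), ufp + 1L, ufp + ulen),
    chrom = "chrY", strand = "+", five_prime = ufp, length = ulen,
    molecules = as.integer(tab), stringsAsFactors = FALSE
  )
  out[order(out$five_prime, out$length), , drop = FALSE]
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated biogenesis truth:\n")
  print(table(x$small$class))
  cat(sprintf("%d long RNA species (%d pre-pre-piRNA cut sites)\n",
              nrow(x$long), length(x$cut_sites)))
  invisible(x)
}

#' Sample per-species read counts for one library
#'
#' Draws a multinomial read sample over the truth molecule pool, emulating
#' sequencing a library to fixed depth without generating read sequences.
#' Uses the current RNG state (seed upstream for reproducibility).
#'
#' @param truth A `sim_truth`.
#' @param depth Total reads to draw.
#' @param which `"small"` or `"long"` species table.
#' @return The species table with an added `count` column.
#' @export
sample_read_counts <- function(truth, depth, which = c("small", "long")) {
  which <- match.arg(which)
  df <- truth[[which]]
  df$count <- as.vector(rmultinom(1, depth, prob = df$molecules))
  df
}

#' Emit truth-tagged FASTQ read sets
#'
#' Wraps each sampled small RNA molecule in the split-UMI adapter grammar
#' (independent random UMIs and 5'-adapter variant per read), draws
#' per-library read counts by multinomial sampling at the configured depths,
#' injects substitution errors, and emits long-RNA reads as 5'-anchored
#' sequences preceded by the 15-nt degenerate block. Each read id is keyed
#' into a truth table.
#'
#' @param truth A [simulate_biogenesis()] result.
#' @param gen The matching [build_genome()] result.
#' @param cfg The generating [sim_config()].
#' @return List with `small_libs` and `long_libs`; each library is a list of
#'   `reads` (named character vector) and `truth` (data.frame id, class,
#'   sequence, species row index).
#' @export
emit_reads <- function(truth, gen, cfg = truth$cfg) {
  set.seed(derive_seed(cfg$seed, "reads"))
  small_libs <- lapply(seq_len(cfg$n_small_libs), function(lib) {
    counts <- as.vector(rmultinom(1, cfg$depth_small,
                                  prob = truth$small$molecules))
    idx <- rep(seq_len(nrow(truth$small)), counts)
    inserts <- truth$small$sequence[idx]
    n <- length(idx)
    reads <- wrap_small_reads(inserts)
    reads <- inject_errors(reads, cfg$sequencing_error_rate)
    names(reads) <- sprintf("s%d_r%06d", lib, seq_len(n))
    list(reads = reads,
         truth = data.frame(id = names(reads), species = idx,
                            class = truth$small$class[idx],
                            sequence = inserts, stringsAsFactors = FALSE))
  })

  genome_chr <- setNames(as.character(gen$genome), names(gen$genome))
  long_libs <- lapply(seq_len(cfg$n_long_libs), function(lib) {
    counts <- as.vector(rmultinom(1, cfg$depth_long,
                                  prob = truth$long$molecules))
    idx <- rep(seq_len(nrow(truth$long)), counts)
    n <- length(idx)
    L <- pmin(truth$long$length[idx], cfg$long_read_length)
    fp <- truth$long$five_prime[idx]
    chrom_seq <- genome_chr[truth$long$chrom[idx]]
    plus <- truth$long$strand[idx] == "+"
    body <- character(n)
    body[plus] <- substr(chrom_seq[plus], fp[plus] + 1L, fp[plus] + L[plus])
    if (any(!plus)) {
      body[!plus] <- revcomp(substr(chrom_seq[!plus],
                                    fp[!plus] - L[!plus] + 2L,
                                    fp[!plus] + 1L))
    }
    reads <- paste0(random_block(n, 15L), body)
    reads <- inject_errors(reads, cfg$sequencing_error_rate)
    names(reads) <- sprintf("l%d_r%06d", lib, seq_len(n))
    list(reads = reads,
         truth = data.frame(id = names(reads), species = idx,
                            class = truth$long$class[idx],
                            stringsAsFactors = FALSE))
  })
  list(small_libs = small_libs, long_libs = long_libs)
}

# Random fixed-width blocks as a character vector.
random_block <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

wrap_small_reads <- function(inserts) {
  n <- length(inserts)
  if (n == 0L) return(character(0))
  u5 <- random_block(n, 9L)
  u3 <- random_block(n, 9L)
  variant <- sample(c("A", "B"), n, replace = TRUE)
  sp1 <- ifelse(variant == "A", "CGA", "ATC")
  sp2 <- ifelse(variant == "A", "TCA", "AGT")
  b5 <- paste0(substr(u5, 1, 3), sp1, substr(u5, 4, 6), sp2,
               substr(u5, 7, 9))
  b3 <- paste0(substr(u3, 1, 3), "GTC", substr(u3, 4, 6), "TAG",
               substr(u3, 7, 9))
  paste0(b5, inserts, b3, SMALL_RNA_ADAPTER3)
}

inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample(length(chars), nerr[i])
    chars[at] <- vapply(chars[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}
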