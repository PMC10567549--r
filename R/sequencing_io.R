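# Adapter/UMI read structure of the small RNA libraries.
#
# A sequencing read is laid out as
#   [NNN s1 NNN s2 NNN]  insert  [NNN GTC NNN TAG NNN]  TGGAATTCTCGGGTGCCAAGG...
# where the three N-triplets on each side concatenate to a 9-nt unique
# molecular identifier (UMI) and (s1, s2) is (CGA, TCA) for 5' adapter
# variant A or (ATC, AGT) for variant B.

SMALL_RNA_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5_SPACERS <- list(A = c("CGA", "TCA"), B = c("ATC", "AGT"))
ADAPTER3_SPACERS <- c("GTC", "TAG")

#' Parse small RNA reads carrying split-UMI adapters
#'
#' Locates the constant 3' adapter, extracts the insert lying between the two
#' 15-nt degenerate blocks, and reassembles the 9-nt UMIs from the N-triplets
#' embedded in each block. The fixed spacer triplets (`CGA`/`TCA` or
#' `ATC`/`AGT` on the 5' side, `GTC`/`TAG` on the 3' side) are validated
#' allowing at most `max_spacer_mismatch` mismatches in total, which tolerates
#' occasional sequencing errors without accepting arbitrary sequence.
#'
#' @param reads Character vector of read sequences (or a
#'   [Biostrings::DNAStringSet]); names are carried through as read ids.
#' @param adapter3 Constant 3' adapter sequence; at least the first 10 nt
#'   must be present in the read.
#' @param max_spacer_mismatch Maximum total mismatches across the six spacer
#'   triplets (default 1).
#' @return A data.frame with one row per read: `id`, `insert`, `umi5`,
#'   `umi3`, `variant` (`"A"`/`"B"`), and `status` (`"ok"`, `"no_adapter"`,
#'   `"bad_umi_structure"` or `"empty_insert"`). Non-`ok` rows have `NA`
#'   inserts.
#' @examples
#' r <- paste0("AAACGAAAATCAAAA", "TGCTTGGACTACATATGGTTG",
#'             "CCCGTCCCCTAGCCC", "TGGAATTCTCGGGTGCCAAGG")
#' parse_small_rna_reads(r)
#' @export
parse_small_rna_reads <- function(reads, adapter3 = SMALL_RNA_ADAPTER3,
                                  max_spacer_mismatch = 1L) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  n <- length(reads)
  seed <- substr(adapter3, 1, 10)

  # First adapter-seed occurrence leaving room for the two 15-nt degenerate
  # blocks upstream (1-based position >= 31; position 31 means an empty
  # insert, reported as such).
  pos <- vapply(gregexpr(seed, reads, fixed = TRUE), function(m) {
    m <- m[m >= 31L]
    if (length(m)) m[1] else NA_integer_
  }, integer(1))

  status <- rep("ok", n)
  status[is.na(pos)] <- "no_adapter"
  insert <- rep(NA_character_, n)
  umi5 <- rep(NA_character_, n)
  umi3 <- rep(NA_character_, n)
  variant <- rep(NA_character_, n)

  ok <- !is.na(pos)
  if (any(ok)) {
    p <- pos[ok]
    s <- reads[ok]
    empty <- p - 16L < 16L
    b5 <- substr(s, 1L, 15L)
    b3 <- substr(s, p - 15L, p - 1L)
    sp1 <- substr(b5, 4L, 6L); sp2 <- substr(b5, 10L, 12L)
    sp3 <- substr(b3, 4L, 6L); sp4 <- substr(b3, 10L, 12L)
    mmA <- string_mismatches(sp1, rep("CGA", length(sp1))) +
      string_mismatches(sp2, rep("TCA", length(sp2)))
    mmB <- string_mismatches(sp1, rep("ATC", length(sp1))) +
      string_mismatches(sp2, rep("AGT", length(sp2)))
    mm3 <- string_mismatches(sp3, rep("GTC", length(sp3))) +
      string_mismatches(sp4, rep("TAG", length(sp4)))
    var <- ifelse(mmA <= mmB, "A", "B")
    bad <- pmin(mmA, mmB) + mm3 > max_spacer_mismatch

    st <- rep("ok", length(p))
    st[bad] <- "bad_umi_structure"
    st[empty] <- "empty_insert"
    status[ok] <- st

    keep <- st == "ok"
    ins <- substr(s, 16L, p - 16L)
    insert[ok][keep] <- ins[keep]
    umi5[ok][keep] <- paste0(substr(b5, 1, 3), substr(b5, 7, 9),
                             substr(b5, 13, 15))[keep]
    umi3[ok][keep] <- paste0(substr(b3, 1, 3), substr(b3, 7, 9),
                             substr(b3, 13, 15))[keep]
    variant[ok][keep] <- var[keep]
  }

  data.frame(id = ids, insert = insert, umi5 = umi5, umi3 = umi3,
             variant = variant, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse PCR duplicates by insert + UMI pair
#'
#' Reads sharing the same `(insert, umi5, umi3)` triple are PCR copies of one
#' ligation event and collapse to a single observation; the species count of
#' an insert is the number of distinct UMI pairs that carried it. Duplicate
#' removal happens before genome mapping, so the key is the insert sequence,
#' not a genomic position. The result is independent of input order.
#'
#' @param parsed Data.frame from [parse_small_rna_reads()] (rows with
#'   `status != "ok"` are dropped).
#' @return A data.frame of species: `sequence`, `count`, sorted by sequence.
#' @export
deduplicate <- function(parsed) {
  stopifnot(all(c("insert", "umi5", "umi3") %in% names(parsed)))
  ok <- parsed[!is.na(parsed$insert) &
                 (parsed$status %||% "ok") == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  key <- paste(ok$insert, ok$umi5, ok$umi3, sep = "\r")
  uniq <- ok[!duplicated(key), , drop = FALSE]
  tab <- table(uniq$insert)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$sequence), , drop = FALSE]
}

#' Classify species as spike-in, rRNA, or retained
#'
#' A species exactly matching one of the synthetic spike-in oligos is labelled
#' `spikein` (spike-ins take precedence); a species aligning within any rRNA
#' reference with at most one mismatch, on either strand, is labelled `rrna`;
#' everything else is `retained` for downstream analysis.
#'
#' @param species Data.frame with `sequence` and `count` columns
#'   ([deduplicate()] output).
#' @param rrna_refs,spike_refs [Biostrings::DNAStringSet] (or named character
#'   vectors) of reference sequences.
#' @return `species` with added `class` and `spike_id` columns.
#' @export
classify_reads <- function(species, rrna_refs, spike_refs) {
  rrna_refs <- as_dna_set(rrna_refs)
  spike_refs <- as_dna_set(spike_refs)
  if (length(rrna_refs) == 0L || length(spike_refs) == 0L) {
    stop("reference sets must be non-empty")
  }
  cls <- rep("retained", nrow(species))
  spike_id <- rep(NA_character_, nrow(species))

  hit <- match(species$sequence, as.character(spike_refs))
  cls[!is.na(hit)] <- "spikein"
  spike_id[!is.na(hit)] <- names(spike_refs)[hit[!is.na(hit)]]

  rrna_chr <- as.character(rrna_refs)
  rrna_rc <- revcomp(rrna_chr)
  todo <- which(cls == "retained")
  for (i in todo) {
    s <- species$sequence[i]
    w <- nchar(s)
    for (j in seq_along(rrna_chr)) {
      if (w > nchar(rrna_chr[j])) next
      if (length(scan_ungapped(rrna_chr[j], s, 1L)$start) > 0L ||
          length(scan_ungapped(rrna_rc[j], s, 1L)$start) > 0L) {
        cls[i] <- "rrna"
        break
      }
    }
  }
  species$class <- cls
  species$spike_id <- spike_id
  species
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(x)
}

#' Spike-in calibration for absolute quantification
#'
#' An equimolar mix of six synthetic 5'-phosphorylated RNA oligos is added to
#' each sample before library construction. The number of sequenced reads per
#' spiked molecule is estimated as the median of the per-species spike read
#' counts (robust to a single failed ligation) divided by the known number of
#' molecules spiked per species.
#'
#' @param spike_counts Numeric vector of post-deduplication read counts, one
#'   per spike species (normally six).
#' @param molecules_per_species Molecules of each spike species added to the
#'   sample aliquot.
#' @param total_rna_pg Mass of total RNA in the aliquot, in picograms.
#' @return An object of class `spike_calibration`.
#' @export
spike_calibration <- function(spike_counts, molecules_per_species,
                              total_rna_pg) {
  stopifnot(molecules_per_species > 0, total_rna_pg > 0)
  if (all(spike_counts == 0)) {
    stop_pp("uncalibrated", "all spike-in read counts are zero")
  }
  structure(list(
    spike_counts = spike_counts,
    molecules_per_species = molecules_per_species,
    total_rna_pg = total_rna_pg,
    reads_per_molecule = median(spike_counts) / molecules_per_species
  ), class = "spike_calibration")
}

#' @export
print.spike_calibration <- function(x, ...) {
  cat("Spike-in calibration:", length(x$spike_counts), "species;",
      format(x$molecules_per_species, big.mark = ","), "molecules each;",
      signif(x$reads_per_molecule, 4), "reads per molecule;",
      x$total_rna_pg, "pg total RNA\n")
  invisible(x)
}

#' Absolute abundance in molecules per 10 pg total RNA
#'
#' @param target_read_count Post-deduplication read count(s) of the target
#'   species or species group.
#' @param calib A [spike_calibration()] object.
#' @return Numeric: molecules per 10 pg total RNA (0 iff the read count is 0).
#' @examples
#' cal <- spike_calibration(rep(10, 6), 1e6, 100)
#' absolute_abundance(5, cal) # 5e4 per 10 pg
#' @export
absolute_abundance <- function(target_read_count, calib) {
  stopifnot(inherits(calib, "spike_calibration"))
  (target_read_count / calib$reads_per_molecule) * (10 / calib$total_rna_pg)
}

#' Read FASTQ sequences
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub(" .*", "", names(x))
  out
}

#' Write sequences as FASTQ (constant quality)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

#' Remove the degenerate 5' block of long RNA reads
#'
#' Long (degradome) libraries carry only the 15-nt degenerate block of the 5'
#' adapter at the start of read 1; no 3' UMI is expected.
#'
#' @param reads Character vector of read-1 sequences.
#' @param n Number of leading nucleotides to strip (default 15).
#' @return Character vector of trimmed reads (names preserved).
#' @export
strip_degenerate_block <- function(reads, n = 15L) {
  out <- substr(reads, n + 1L, nchar(reads))
  names(out) <- names(reads)
  out
}
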