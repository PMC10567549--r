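# Desk-scale ungapped alignment and feature annotation. All coordinates are
# 0-based half-open; the 5' end of a minus-strand footprint is end - 1.

#' Ungapped alignment with non-templated 3'-tail detection
#'
#' Reports every position on either strand of the reference where the full
#' sequence matches with at most `max_mm` mismatches. When a sequence has no
#' full-length hit, progressively shorter 5' prefixes (down to `min_prefix`)
#' are matched and the unmatched 3' remainder (at most `max_tail` nt) is
#' recorded as a non-templated tail, mirroring how small RNA 3'-end tailing is
#' accommodated. An `N` in a read matches nothing.
#'
#' @param sequences Character vector of query sequences (duplicates are
#'   aligned once).
#' @param genome Named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param max_mm Maximum mismatches on the matched portion (default 1).
#' @param min_prefix Minimum matched 5' prefix when tailing (default 18).
#' @param max_tail Maximum non-templated tail length (default 4).
#' @return Data.frame: `sequence`, `chrom`, `start`, `end` (0-based
#'   half-open footprint of the matched portion), `strand`, `mismatches`,
#'   `tail_length`, `five_prime`. Unmapped sequences yield no rows.
#' @export
align_ungapped <- function(sequences, genome, max_mm = 1L, min_prefix = 18L,
                           max_tail = 4L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub(" .*", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  contigs <- setNames(as.character(genome), names(genome))

  uniq <- unique(sequences)
  res <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    s <- uniq[k]
    hits <- match_both_strands(s, contigs, max_mm, tail = 0L)
    if (nrow(hits) == 0L && max_tail > 0L) {
      for (tl in seq_len(min(max_tail, nchar(s) - min_prefix))) {
        pre <- substr(s, 1L, nchar(s) - tl)
        hits <- match_both_strands(pre, contigs, max_mm, tail = tl)
        if (nrow(hits) > 0L) break
      }
    }
    if (nrow(hits) > 0L) {
      hits$sequence <- s
      res[[k]] <- hits
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      tail_length = integer(0), five_prime = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[, c("sequence", "chrom", "start", "end", "strand",
                 "mismatches", "tail_length")]
  out$five_prime <- as.integer(five_prime_of(out$start, out$end, out$strand))
  rownames(out) <- NULL
  out
}

match_both_strands <- function(query, contigs, max_mm, tail) {
  pats <- c(`+` = query, `-` = revcomp(query))
  w <- nchar(query)
  rows <- list()
  for (std in c("+", "-")) {
    pat <- pats[[std]]
    for (ci in seq_along(contigs)) {
      m <- scan_ungapped(contigs[[ci]], pat, max_mm)
      if (length(m$start) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(contigs)[ci],
        start = m$start,
        end = m$start + w,
        strand = std,
        mismatches = m$mismatches,
        tail_length = tail,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), tail_length = integer(0)))
  }
  do.call(rbind, rows)
}

#' Assign alignments to annotated features
#'
#' Each alignment is labelled with the overlapping annotation interval of the
#' highest-precedence class (`pirna_locus` > `insertion` > `transposon` >
#' `genic`); alignments overlapping nothing are labelled `"none"`. For
#' multi-mapping species the read count is distributed over the alignments of
#' the best class: fractionally (`policy = "fractional"`, default, weight
#' `count / n`) so that total assigned weight per species equals its read
#' count, or once per feature (`policy = "per_feature_once"`, full count to
#' every distinct feature of the best class).
#'
#' Annotation intervals with strand `"*"` match alignments on either strand;
#' stranded intervals require the alignment strand to agree.
#'
#' @param alignments Data.frame from [align_ungapped()] with a `count` column
#'   (per-species read count; defaults to 1).
#' @param annotation Data.frame with `chrom`, `start`, `end`, `strand`,
#'   `name`, `class` (0-based half-open).
#' @param policy Multi-mapper weighting policy.
#' @return `alignments` with added `feature`, `feature_class` and `weight`
#'   columns.
#' @export
assign_feature <- function(alignments, annotation,
                           policy = c("fractional", "per_feature_once")) {
  policy <- match.arg(policy)
  if (nrow(alignments) == 0L) {
    alignments$feature <- character(0)
    alignments$feature_class <- character(0)
    alignments$weight <- numeric(0)
    return(alignments)
  }
  if (is.null(alignments$count)) alignments$count <- 1
  precedence <- c(pirna_locus = 1, insertion = 2, transposon = 3,
                  genic = 4, none = 99)

  aln_gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start + 1L, alignments$end),
    strand = alignments$strand
  )
  ann_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand
  )
  ov <- GenomicRanges::findOverlaps(aln_gr, ann_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  strand_ok <- annotation$strand[sh] == "*" |
    annotation$strand[sh] == alignments$strand[qh]
  qh <- qh[strand_ok]
  sh <- sh[strand_ok]

  feature <- rep("none", nrow(alignments))
  fclass <- rep("none", nrow(alignments))
  if (length(qh)) {
    ord <- order(qh, precedence[annotation$class[sh]], annotation$name[sh])
    first <- !duplicated(qh[ord])
    feature[qh[ord][first]] <- annotation$name[sh[ord][first]]
    fclass[qh[ord][first]] <- annotation$class[sh[ord][first]]
  }
  alignments$feature <- feature
  alignments$feature_class <- fclass

  # Per-species weighting restricted to the best class present.
  alignments$weight <- 0
  for (s in unique(alignments$sequence)) {
    idx <- which(alignments$sequence == s)
    best <- min(precedence[fclass[idx]])
    keep <- idx[precedence[fclass[idx]] == best]
    cnt <- alignments$count[idx[1]]
    if (policy == "fractional") {
      alignments$weight[keep] <- cnt / length(keep)
    } else {
      # full count once per distinct feature; duplicates within a feature
      # still share fractionally so a feature never gets more than `cnt`.
      for (f in unique(feature[keep])) {
        fi <- keep[feature[keep] == f]
        alignments$weight[fi] <- cnt / length(fi)
      }
    }
  }
  alignments
}

#' Length profile of assigned small RNA species
#'
#' @param species Data.frame with `sequence` (or `length`) and `count`
#'   columns, optionally a `feature` column.
#' @param feature Optional feature label to restrict to.
#' @param length_range Integer range of lengths to tabulate.
#' @param normalize Return fractions instead of read counts.
#' @return Data.frame `length`, `reads`.
#' @export
length_profile <- function(species, feature = NULL,
                           length_range = c(15L, 54L), normalize = FALSE) {
  if (!is.null(feature) && !is.null(species$feature)) {
    species <- species[species$feature == feature, , drop = FALSE]
  }
  len <- species$length %||% nchar(species$sequence)
  lv <- seq(length_range[1], length_range[2])
  reads <- vapply(lv, function(l) sum(species$count[len == l]), numeric(1))
  if (normalize && sum(reads) > 0) reads <- reads / sum(reads)
  data.frame(length = lv, reads = reads)
}

#' Positional nucleotide composition with background
#'
#' Read-count-weighted base fractions at 5'-anchored positions (position 1 is
#' the 5'-terminal nucleotide), against a background pooled over every
#' position of every species (a species of length L contributes L * count
#' observations). `T` stands for uridine in DNA-space reads. Species shorter
#' than a requested position are excluded from that position (and counted in
#' `n_excluded`).
#'
#' @param species Data.frame with `sequence` and `count`.
#' @param positions Integer positions to profile (default 1 and 10).
#' @return List with `per_position` (position x base fraction matrix),
#'   `background` (named base fractions), `n_used` and `n_excluded` read
#'   counts per position.
#' @export
nt_composition <- function(species, positions = c(1L, 10L)) {
  stopifnot(nrow(species) > 0)
  bases <- c("A", "C", "G", "T")
  seqs <- species$sequence
  cnt <- species$count
  len <- nchar(seqs)

  lf <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                    letters = bases)
  bg_counts <- colSums(lf * cnt)
  background <- bg_counts / sum(cnt * len)

  per <- matrix(NA_real_, nrow = length(positions), ncol = length(bases),
                dimnames = list(position = positions, base = bases))
  n_used <- n_excl <- setNames(numeric(length(positions)),
                               as.character(positions))
  for (i in seq_along(positions)) {
    p <- positions[i]
    sel <- len >= p
    n_used[i] <- sum(cnt[sel])
    n_excl[i] <- sum(cnt[!sel])
    if (n_excl[i] > 0) {
      pp_log(sprintf("nt_composition: %d reads shorter than position %d excluded",
                     n_excl[i], p))
    }
    if (!any(sel)) next
    b <- substr(seqs[sel], p, p)
    per[i, ] <- vapply(bases, function(x) sum(cnt[sel][b == x]),
                       numeric(1)) / sum(cnt[sel])
  }
  list(per_position = per, background = background,
       n_used = n_used, n_excluded = n_excl)
}

#' Read a BED6 annotation with feature classes
#'
#' The BED name field is interpreted as `name|class` where `class` is one of
#' `pirna_locus`, `insertion`, `transposon`, `genic`. Coordinates are kept
#' 0-based half-open.
#'
#' @param path BED file path.
#' @return Annotation data.frame as used by [assign_feature()].
#' @export
read_annotation_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name_field", "score",
                       "strand")
  parts <- strsplit(bed$name_field, "|", fixed = TRUE)
  data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand,
    name = vapply(parts, `[`, character(1), 1L),
    class = vapply(parts, function(x) if (length(x) >= 2) x[2] else "genic",
                   character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write an annotation data.frame as BED6
#'
#' @param annotation Annotation data.frame (`chrom`, `start`, `end`,
#'   `strand`, `name`, `class`).
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$start, annotation$end,
                    paste(annotation$name, annotation$class, sep = "|"),
                    0L, annotation$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
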