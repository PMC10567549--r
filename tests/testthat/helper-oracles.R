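# Independent oracles used to verify the package's implementations. These are
# deliberately naive (O(n^2) enumeration, raw byte comparison, explicit
# formula sums) and share no code with the functions they check.

rc_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

rand_dna_chr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# All 0-based starts where pattern matches subject with <= max_mm
# mismatches, by direct byte comparison over every offset. Pattern Ns never
# match.
oracle_scan <- function(subject, pattern, max_mm) {
  g <- charToRaw(subject)
  p <- charToRaw(pattern)
  L <- length(g)
  w <- length(p)
  if (w == 0L || w > L) {
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  M <- L - w + 1L
  idx <- outer(seq_len(w), 0:(M - 1L), "+")
  eq <- (matrix(g[idx], nrow = w) == p) & (p != charToRaw("N"))
  mm <- w - colSums(eq)
  keep <- mm <= max_mm
  data.frame(start = which(keep) - 1L, mismatches = as.integer(mm[keep]))
}

# Exhaustive re-implementation of the ungapped aligner contract: full-length
# hits first, then progressively longer tails on the 5' prefix.
oracle_align <- function(seqs, contigs, max_mm = 1L, min_prefix = 18L,
                         max_tail = 4L) {
  res <- list()
  for (s in unique(seqs)) {
    hit <- NULL
    for (tl in 0:min(max_tail, nchar(s) - min_prefix)) {
      q <- substr(s, 1L, nchar(s) - tl)
      rows <- list()
      for (std in c("+", "-")) {
        pat <- if (std == "+") q else rc_chr(q)
        for (cn in names(contigs)) {
          h <- oracle_scan(contigs[[cn]], pat, max_mm)
          if (nrow(h)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sequence = s, chrom = cn, start = h$start,
              end = h$start + nchar(q), strand = std,
              mismatches = h$mismatches, tail_length = tl,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(rows)) {
        hit <- do.call(rbind, rows)
        break
      }
    }
    if (!is.null(hit)) res[[s]] <- hit
  }
  if (!length(res)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      tail_length = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

canon_aln <- function(df) {
  df <- df[, c("sequence", "chrom", "start", "end", "strand", "mismatches",
               "tail_length")]
  df <- df[order(df$sequence, df$chrom, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# All-pairs 5'-5' overlap enumeration.
oracle_spectrum <- function(a, b, max_offset = 20L, weighting = "read") {
  counts <- stats::setNames(numeric(max_offset + 1L), 0:max_offset)
  wa <- if (weighting == "read") a$count else rep(1, nrow(a))
  wb <- if (weighting == "read") b$count else rep(1, nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (a$strand[i] == b$strand[j]) next
      if (a$strand[i] == "+") {
        P <- a$five_prime[i]
        G <- b$five_prime[j]
      } else {
        P <- b$five_prime[j]
        G <- a$five_prime[i]
      }
      o <- G - P + 1L
      if (o >= 0L && o <= max_offset) {
        counts[as.character(o)] <- counts[as.character(o)] + wa[i] * wb[j]
      }
    }
  }
  counts
}

rand_end_set <- function(n, chroms = c("cA", "cB"), span = 60L) {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    five_prime = sample.int(span, n, replace = TRUE),
    count = sample.int(5L, n, replace = TRUE)
  )
}

# Pearson autocorrelation at one lag, written as explicit sums.
oracle_autocorr <- function(x, lag) {
  a <- x[1:(length(x) - lag)]
  b <- x[(1 + lag):length(x)]
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
  num / den
}

# Comb profile: unit spikes every `period` positions.
comb_profile <- function(period, L = 150L) {
  v <- numeric(L)
  v[seq(1L, L, by = period)] <- 1
  v
}
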