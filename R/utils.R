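# Internal helpers: coordinates are 0-based, half-open throughout the
# package (BED convention). The 5' end of a minus-strand footprint is the
# interval's last base (end - 1).

`%||%` <- function(a, b) if (is.null(a)) b else a

pp_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("pirnaphase.verbose", FALSE))) {
    message(sprintf("[%s] ", level), ...)
  }
  invisible(NULL)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a stage tag to a deterministic 32-bit seed so that
#' every stage of a simulation or pipeline run draws from its own stream.
#'
#' @param seed Integer master seed.
#' @param tag Character stage label.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  code <- utf8ToInt(tag)
  h <- sum(code * seq_along(code)) %% 104729
  as.integer((abs(seed) * 1009 + h * 31 + 17) %% 2147483647)
}

#' Genomic 5' end of an aligned footprint
#'
#' @param start,end 0-based half-open interval bounds.
#' @param strand "+" or "-".
#' @return 0-based coordinate of the first transcribed nucleotide.
#' @export
five_prime_of <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

# Reverse complement for plain character vectors (DNA alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s).
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute each position with probability `rate` by a different base.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# Number of mismatching characters between equal-width strings (vectorized).
string_mismatches <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  out <- integer(length(a))
  w <- unique(nchar(a))
  for (width in w) {
    idx <- which(nchar(a) == width)
    mm <- integer(length(idx))
    for (p in seq_len(width)) {
      mm <- mm + (substr(a[idx], p, p) != substr(b[idx], p, p))
    }
    out[idx] <- mm
  }
  out
}

# 0-based half-open genomic substring of a named contig set.
contig_substring <- function(genome, chrom, start, end) {
  substr(as.character(genome[[chrom]]), start + 1L, end)
}

stop_pp <- function(code, msg) {
  stop(structure(
    class = c(code, "pirnaphase_error", "error", "condition"),
    list(message = sprintf("%s: %s", code, msg), call = sys.call(-1))
  ))
}
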