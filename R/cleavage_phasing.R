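# Core biogenesis statistics: 5'-5' overlap spectra with the Z10 standard
# score, 5'-monophosphorylated long RNA species, pre-pre-piRNA calling at the
# transposon-insertion junction, phasing metaplots and autocorrelation.
#
# Overlap convention: for a plus-strand 5' end at P and a minus-strand 5' end
# at G on the same chromosome (both 0-based), the 5'-5' overlap is
# o = G - P + 1 nt. o = 10 is the ping-pong/slicing geometry: nucleotide g10
# of the guide pairs with the first nucleotide of the cleavage product, whose
# 5' phosphate is the scissile phosphate between target nucleotides t10/t11.

#' Merge long RNA reads into 5'-end species
#'
#' Reads with the same genomic 5' end (same chromosome and strand) are merged
#' to represent a single 5'-monophosphorylated RNA species; the species read
#' count is the number of merged reads and its length the longest observed
#' extent.
#'
#' @param alignments Data.frame of read alignments with `chrom`, `start`,
#'   `end`, `strand` (0-based half-open) and optionally `count` (reads per
#'   row, default 1).
#' @return Data.frame of species: `chrom`, `strand`, `five_prime`, `length`,
#'   `read_count`, `start`, `end` (footprint of the longest extent).
#' @export
merge_long_rnas <- function(alignments) {
  if (is.null(alignments$count)) alignments$count <- 1L
  fp <- five_prime_of(alignments$start, alignments$end, alignments$strand)
  extent <- alignments$end - alignments$start
  key <- paste(alignments$chrom, alignments$strand, fp, sep = "\r")
  sp <- split(seq_len(nrow(alignments)), key)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(
      chrom = alignments$chrom[idx[1]],
      strand = alignments$strand[idx[1]],
      five_prime = as.integer(fp[idx[1]]),
      length = as.integer(max(extent[idx])),
      read_count = as.integer(sum(alignments$count[idx])),
      stringsAsFactors = FALSE
    )
  }))
  out$start <- ifelse(out$strand == "+", out$five_prime,
                      out$five_prime - out$length + 1L)
  out$end <- out$start + out$length
  out <- out[order(out$chrom, out$strand, out$five_prime), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 5'-5' overlap spectrum between opposite-strand 5'-end sets
#'
#' Counts, for every overlap offset 0..`max_offset`, the weighted number of
#' pairs formed by a 5' end from `a` and an opposite-strand 5' end from `b`
#' on the same chromosome. Under read weighting the pair contributes the
#' product of the two read counts; under species weighting each pair
#' contributes 1.
#'
#' @param a,b Data.frames with `chrom`, `strand`, `five_prime`, and `count`
#'   (read weighting; a missing column counts 1 per species).
#' @param max_offset Largest overlap offset tabulated (default 20).
#' @param weighting `"read"` (default) or `"species"`.
#' @return Object of class `overlap_spectrum`: list with `counts` (named
#'   vector for offsets 0..max_offset), `focus`, `weighting`.
#' @export
overlap_spectrum <- function(a, b, max_offset = 20L,
                             weighting = c("read", "species")) {
  weighting <- match.arg(weighting)
  counts <- setNames(numeric(max_offset + 1L), 0:max_offset)
  wa <- spectrum_weights(a, weighting)
  wb <- spectrum_weights(b, weighting)

  accumulate <- function(plus, minus) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return(invisible(NULL))
    for (chr in intersect(unique(plus$chrom), unique(minus$chrom))) {
      p <- plus[plus$chrom == chr, ]
      m <- minus[minus$chrom == chr, ]
      tp <- tapply(p$w, p$five_prime, sum)
      tm <- tapply(m$w, m$five_prime, sum)
      cp <- as.numeric(names(tp))
      for (o in 0:max_offset) {
        idx <- match(cp + o - 1, as.numeric(names(tm)))
        hit <- !is.na(idx)
        if (any(hit)) {
          counts[as.character(o)] <<- counts[as.character(o)] +
            sum(tp[hit] * tm[idx[hit]])
        }
      }
    }
  }
  accumulate(wa[wa$strand == "+", ], wb[wb$strand == "-", ])
  accumulate(wb[wb$strand == "+", ], wa[wa$strand == "-", ])

  structure(list(counts = counts, focus = 10L, weighting = weighting),
            class = "overlap_spectrum")
}

spectrum_weights <- function(x, weighting) {
  w <- if (weighting == "read") {
    x$count %||% x$read_count %||% rep(1, nrow(x))
  } else {
    rep(1, nrow(x))
  }
  data.frame(chrom = x$chrom, strand = x$strand, five_prime = x$five_prime,
             w = w, stringsAsFactors = FALSE)
}

#' @export
print.overlap_spectrum <- function(x, ...) {
  cat("5'-5' overlap spectrum (", x$weighting, "-weighted), offsets 0-",
      length(x$counts) - 1L, "\n", sep = "")
  print(round(x$counts, 2))
  if (!is.null(x$z)) {
    cat(sprintf("Z%d = %.3g, two-sided P = %.3g\n", x$focus, x$z, x$p))
  }
  invisible(x)
}

#' Standard score of the focus overlap (Z10)
#'
#' The focus count is compared with the background of all displayed offsets
#' except the focus; z is the number of population standard deviations the
#' focus count lies from the background mean, with a two-sided standard
#' normal tail probability. A uniform spectrum gives z = 0, p = 1; a
#' zero-variance background with a deviating focus is degenerate.
#'
#' @param spectrum An `overlap_spectrum` or a named numeric vector of counts
#'   (names = offsets).
#' @param focus Offset of interest (default 10).
#' @return List with `z`, `p`, `focus`, `background_mean`, `background_sd`.
#'   When `spectrum` is an `overlap_spectrum` the object is returned with
#'   `z`/`p` fields attached (invisibly accessible via `$z`, `$p`).
#' @export
z_score <- function(spectrum, focus = 10L) {
  counts <- if (inherits(spectrum, "overlap_spectrum")) spectrum$counts
            else spectrum
  if (is.null(names(counts))) names(counts) <- seq_along(counts) - 1L
  fkey <- as.character(focus)
  stopifnot(fkey %in% names(counts))
  bg <- counts[names(counts) != fkey]
  mu <- mean(bg)
  sdp <- sqrt(mean((bg - mu)^2))
  if (sdp == 0) {
    if (counts[fkey] == mu) {
      z <- 0
    } else {
      stop_pp("degenerate_background",
              "background has zero standard deviation")
    }
  } else {
    z <- (counts[fkey] - mu) / sdp
  }
  z <- unname(z)
  p <- 2 * pnorm(-abs(z))
  if (inherits(spectrum, "overlap_spectrum")) {
    spectrum$z <- z
    spectrum$p <- p
    spectrum$background_mean <- mu
    spectrum$background_sd <- sdp
    return(spectrum)
  }
  list(z = z, p = p, focus = focus, background_mean = mu, background_sd = sdp)
}

#' Aggregate Z over dataset permutations
#'
#' When several small RNA and long RNA datasets are available, a spectrum is
#' computed for every (small, long) dataset permutation. Two aggregate
#' statistics are reported: the mean of the per-permutation z values and the
#' z of the summed spectrum; both are returned because published displays do
#' not always state which was used.
#'
#' @param spectra List of `overlap_spectrum` objects (one per permutation).
#' @param focus Focus offset.
#' @return List with `z_mean`, `p_mean` (two-sided normal tail of `z_mean`),
#'   `z_pooled`, `p_pooled`, and `per_permutation` z values.
#' @export
permutation_z <- function(spectra, focus = 10L) {
  zs <- vapply(spectra, function(s) z_score(s, focus)$z, numeric(1))
  pooled <- Reduce(`+`, lapply(spectra, `[[`, "counts"))
  zp <- z_score(pooled, focus)
  list(z_mean = mean(zs), p_mean = 2 * pnorm(-abs(mean(zs))),
       z_pooled = zp$z, p_pooled = zp$p, per_permutation = zs)
}

#' Call slicer cleavage products among long RNA species
#'
#' A long RNA species is a putative cleavage product when at least one
#' opposite-strand guide has a 5'-5' overlap of exactly 10 nt with the
#' species' 5' end, i.e. its 5' phosphate sits at the scissile position
#' between target nucleotides t10 and t11 of a guide.
#'
#' @param longs Long RNA species ([merge_long_rnas()] output).
#' @param guides Data.frame of guide small RNA 5' ends (`chrom`, `strand`,
#'   `five_prime`).
#' @return The subset of `longs` with guide support (possibly empty).
#' @export
call_cleavage_products <- function(longs, guides) {
  if (nrow(longs) == 0L || nrow(guides) == 0L) {
    return(longs[integer(0), , drop = FALSE])
  }
  called <- logical(nrow(longs))
  for (i in seq_len(nrow(longs))) {
    g <- guides[guides$chrom == longs$chrom[i] &
                  guides$strand != longs$strand[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    called[i] <- if (longs$strand[i] == "+") {
      any(g$five_prime == longs$five_prime[i] + 9L)
    } else {
      any(g$five_prime == longs$five_prime[i] - 9L)
    }
  }
  longs[called, , drop = FALSE]
}

#' Identify pre-pre-piRNAs at the insertion/locus junction
#'
#' Pre-pre-piRNAs are long 5'-monophosphorylated RNAs created by
#' trigger-piRNA-directed slicing inside the transposon-derived 5' leader:
#' species at least `min_len` nt long, on the precursor strand, whose
#' footprint extends beyond the insertion into the locus body and whose 5'
#' end lies within `window` nt of the junction between the insertion and the
#' locus body (the window is centred on the junction, covering the last
#' `window` nt of the insertion and the first `window` nt of the body).
#'
#' @param longs Long RNA species ([merge_long_rnas()] output).
#' @param locus One-row data.frame or list (`chrom`, `start`, `end`,
#'   `strand`) describing the piRNA-producing locus body.
#' @param insertion Interval of the upstream transposon insertion (same
#'   fields; strand ignored). Required.
#' @param window Half-width of the junction window in nt (default 100).
#' @param min_len Minimum species length in nt (default 200, matching the
#'   library's size selection).
#' @return The called subset of `longs` with an added `locus` label column.
#' @export
identify_prepre <- function(longs, locus, insertion, window = 100L,
                            min_len = 200L) {
  if (is.null(insertion)) {
    stop_pp("no_insertion", "insertion annotation is required")
  }
  strand <- locus$strand
  if (strand == "+") {
    junction <- insertion$end
    in_window <- longs$five_prime >= junction - window &
      longs$five_prime < junction + window
    spans_body <- longs$end > junction & longs$start < locus$end
  } else {
    junction <- insertion$start
    in_window <- longs$five_prime >= junction - window &
      longs$five_prime < junction + window
    spans_body <- longs$start < junction & longs$end > locus$start
  }
  called <- longs$chrom == locus$chrom &
    longs$strand == strand &
    longs$length >= min_len &
    in_window & spans_body
  out <- longs[called, , drop = FALSE]
  if (nrow(out)) out$locus <- locus$name %||% "locus"
  attr(out, "junction") <- junction
  out
}

#' Phasing metaplot of piRNA 5'-end density along pre-pre-piRNAs
#'
#' For every permutation of a small RNA dataset with a long RNA dataset, the
#' 5' ends of same-strand piRNAs are tallied at relative positions
#' 0..`L - 1` downstream of each pre-pre-piRNA 5' end. Each per-RNA vector is
#' normalized to unit sum (when non-zero) before averaging across
#' pre-pre-piRNAs, so a single abundant species cannot dominate the profile.
#' The positionwise median and interquartile range across permutations
#' summarize the metaplot.
#'
#' @param long_sets List of pre-pre-piRNA data.frames (or a single
#'   data.frame), e.g. [identify_prepre()] output.
#' @param pirna_sets List of small RNA 5'-end data.frames (`chrom`,
#'   `strand`, `five_prime`, `count`).
#' @param L Metaplot length in nt (default 150).
#' @param weighting `"read"` (5' ends weighted by read count, default) or
#'   `"species"`.
#' @return Object of class `phasing_profile`: `profiles` (permutation x
#'   position matrix), `median`, `q25`, `q75`, `L`, `all_zero`.
#' @export
phasing_metaplot <- function(long_sets, pirna_sets, L = 150L,
                             weighting = c("read", "species")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(long_sets)) long_sets <- list(long_sets)
  if (is.data.frame(pirna_sets)) pirna_sets <- list(pirna_sets)
  stopifnot(length(long_sets) >= 1L, length(pirna_sets) >= 1L)

  perms <- expand.grid(s = seq_along(pirna_sets), l = seq_along(long_sets))
  profiles <- matrix(0, nrow = nrow(perms), ncol = L)
  rownames(profiles) <- paste0("small", perms$s, ".long", perms$l)

  for (k in seq_len(nrow(perms))) {
    smalls <- spectrum_weights(pirna_sets[[perms$s[k]]], weighting)
    longs <- long_sets[[perms$l[k]]]
    if (nrow(longs) == 0L) next
    acc <- numeric(L)
    for (i in seq_len(nrow(longs))) {
      sm <- smalls[smalls$chrom == longs$chrom[i] &
                     smalls$strand == longs$strand[i], , drop = FALSE]
      if (nrow(sm) == 0L) next
      d <- if (longs$strand[i] == "+") {
        sm$five_prime - longs$five_prime[i]
      } else {
        longs$five_prime[i] - sm$five_prime
      }
      keep <- d >= 0 & d < L
      if (!any(keep)) next
      v <- numeric(L)
      tab <- tapply(sm$w[keep], d[keep], sum)
      v[as.integer(names(tab)) + 1L] <- tab
      acc <- acc + v / sum(v)
    }
    profiles[k, ] <- acc / nrow(longs)
  }

  all_zero <- all(profiles == 0)
  if (all_zero) pp_log("phasing_metaplot: all profiles are zero",
                       level = "WARN")
  structure(list(
    profiles = profiles,
    median = apply(profiles, 2, median),
    q25 = apply(profiles, 2, quantile, probs = 0.25, names = FALSE),
    q75 = apply(profiles, 2, quantile, probs = 0.75, names = FALSE),
    L = L, all_zero = all_zero
  ), class = "phasing_profile")
}

#' @export
print.phasing_profile <- function(x, ...) {
  cat("Phasing metaplot:", nrow(x$profiles), "permutation(s),",
      x$L, "positions", if (x$all_zero) "(all zero)" else "", "\n")
  invisible(x)
}

#' Autocorrelation of a positional density profile
#'
#' Pearson correlation of the profile with itself shifted by 1..`max_lag`
#' positions, on overlapping (non-circular) windows. Lags where either window
#' has zero variance are undefined and reported as `NA`.
#'
#' @param profile Numeric density profile, or a `phasing_profile` (its median
#'   profile is used).
#' @param max_lag Largest lag in nt (default 50); the profile must be longer
#'   than `max_lag + 2`.
#' @return Named numeric vector of correlations for lags 1..max_lag.
#' @export
autocorrelate <- function(profile, max_lag = 50L) {
  if (inherits(profile, "phasing_profile")) profile <- profile$median
  L <- length(profile)
  stopifnot(L > max_lag + 2L)
  r <- setNames(rep(NA_real_, max_lag), seq_len(max_lag))
  for (lag in seq_len(max_lag)) {
    x <- profile[1:(L - lag)]
    y <- profile[(1 + lag):L]
    if (sd(x) == 0 || sd(y) == 0) next
    r[lag] <- cor(x, y)
  }
  r
}

#' Estimate the phasing period from an autocorrelation
#'
#' The period is the lag of the maximum correlation within `search_range`
#' (ties broken toward the smaller lag). When a smaller divisor of the peak
#' lag outside the search range carries comparable correlation, the peak may
#' be a harmonic of a shorter true period; this ambiguity is flagged and
#' warned about, never silently resolved.
#'
#' @param autocorr Named correlation vector from [autocorrelate()].
#' @param search_range Inclusive lag range searched (default 15-40 nt).
#' @return Object of class `period_estimate`: `period` (nt), `r` at the
#'   peak, `harmonic` flag.
#' @export
estimate_period <- function(autocorr, search_range = c(15L, 40L)) {
  lags <- as.integer(names(autocorr))
  in_range <- lags >= search_range[1] & lags <= search_range[2] &
    !is.na(autocorr)
  if (!any(in_range)) {
    stop_pp("no_period", "no defined autocorrelation in search range")
  }
  cand <- lags[in_range]
  rvals <- autocorr[in_range]
  peak <- cand[which.max(rvals)]  # which.max takes the first (smallest) lag
  r_peak <- max(rvals)

  harmonic <- FALSE
  if (r_peak > 0) {
    divisors <- peak / seq(2L, peak %/% 2L)
    divisors <- unique(as.integer(divisors[divisors == floor(divisors) &
                                             divisors >= 2]))
    divisors <- divisors[divisors < search_range[1]]
    for (d in divisors) {
      rd <- autocorr[as.character(d)]
      if (!is.na(rd) && rd >= 0.8 * r_peak) {
        harmonic <- TRUE
        break
      }
    }
  }
  if (harmonic) {
    warning("peak lag may be a harmonic of a shorter period",
            call. = FALSE)
  }
  structure(list(period = peak, r = unname(r_peak), harmonic = harmonic),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("Estimated phasing period: %d nt (r = %.3f)%s\n", x$period,
              x$r, if (x$harmonic) " [possible harmonic]" else ""))
  invisible(x)
}
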