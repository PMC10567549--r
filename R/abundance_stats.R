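# Between-genotype abundance comparisons and quantitative PCR arithmetic.

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' For small groups (both sizes <= `exact_max`) the exact two-sided p value
#' is computed by enumerating every arrangement of the pooled observations,
#' using mid-ranks so that ties are handled exactly; for larger groups the
#' normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y Numeric vectors of the two groups.
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return List with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop_pp("insufficient_group", "both groups must be non-empty")
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    arrangements <- combn(n1 + n2, n1)
    Wperm <- colSums(matrix(r[arrangements], nrow = n1))
    p <- mean(abs(Wperm - E) >= abs(W - E) - 1e-9)
    list(statistic = W, p.value = p, method = "exact")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = W, p.value = wt$p.value, method = "normal")
  }
}

#' Compare steady-state abundance between two groups of libraries
#'
#' Fold change of mean per-library abundance (mutant over control) with a
#' two-sided Mann-Whitney p value. Abundances are expected already
#' depth-normalized (e.g. per million non-rRNA genome-mapped reads); the
#' statistic is invariant to any common positive scaling.
#'
#' @param control,mutant Numeric vectors of normalized abundances (one value
#'   per library, or per species under a per-species sampling unit).
#' @return List with `fold_change`, `p.value`, `n_control`, `n_mutant`,
#'   `method`.
#' @export
compare_abundance <- function(control, mutant) {
  if (length(control) == 0L || length(mutant) == 0L) {
    stop_pp("insufficient_group", "both groups must be non-empty")
  }
  ts <- rank_sum_test(control, mutant)
  list(fold_change = mean(mutant) / mean(control),
       p.value = ts$p.value,
       n_control = length(control), n_mutant = length(mutant),
       method = ts$method)
}

#' Relative expression by the 2^-ddCt method with error propagation
#'
#' Per condition, dCt is the mean target Ct minus the mean reference Ct and
#' its standard deviation is propagated as sigma = sqrt(sigma_target^2 +
#' sigma_reference^2); ddCt subtracts the control dCt with another
#' propagation step, and the fold change is 2^-ddCt. With fewer than two
#' replicates the standard deviation is undefined (`NA`) but the fold change
#' is still returned.
#'
#' @param treatment,control Lists (or one-row data.frames) with numeric
#'   replicate vectors `ct_target` and `ct_reference`.
#' @return List with `delta_ct`, `delta_ct_control`, `delta_delta_ct`,
#'   `sigma`, `fold_change`, and the sigma-bounded fold interval
#'   (`fold_low`, `fold_high`).
#' @examples
#' ddct(list(ct_target = c(20, 20.2), ct_reference = c(15, 15.1)),
#'      list(ct_target = c(21, 21.1), ct_reference = c(15, 15.2)))
#' @export
ddct <- function(treatment, control) {
  one <- function(m) {
    stopifnot(all(is.finite(m$ct_target)), all(is.finite(m$ct_reference)))
    s_t <- if (length(m$ct_target) >= 2) sd(m$ct_target) else NA_real_
    s_r <- if (length(m$ct_reference) >= 2) sd(m$ct_reference) else NA_real_
    list(dct = mean(m$ct_target) - mean(m$ct_reference),
         sigma = sqrt(s_t^2 + s_r^2))
  }
  tr <- one(treatment)
  ct <- one(control)
  dd <- tr$dct - ct$dct
  sigma <- sqrt(tr$sigma^2 + ct$sigma^2)
  list(delta_ct = tr$dct, delta_ct_control = ct$dct,
       delta_delta_ct = dd, sigma = sigma,
       fold_change = 2^(-dd),
       fold_low = 2^(-(dd + sigma)), fold_high = 2^(-(dd - sigma)))
}

#' Propagate independent standard deviations
#'
#' @param sigma_y,sigma_z Component standard deviations.
#' @return `sqrt(sigma_y^2 + sigma_z^2)`.
#' @export
propagate_sd <- function(sigma_y, sigma_z) {
  sqrt(sigma_y^2 + sigma_z^2)
}
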