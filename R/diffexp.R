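#' Transcripts-per-million normalization
#'
#' @param count Raw read count(s), >= 0.
#' @param N Library size (total retained reads), > 0.
#' @return `count * 1e6 / N`.
#' @examples
#' tpm(1, 1e6)
#' @export
tpm <- function(count, N) {
  check_flag(all(N > 0), "'N' must be > 0")
  check_flag(all(count >= 0), "'count' must be >= 0")
  count * 1e6 / N
}

# Log-pmf of the count in library 2 given the count in library 1 under
# the Audic-Claverie model: p(y|x) = (N2/N1)^y (x+y)! /
# (x! y! (1+N2/N1)^(x+y+1)). Vectorized over y.
.ac_log_kernel <- function(y, x, N1, N2) {
  lr <- log(N2) - log(N1)
  y * lr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(N2 / N1)
}

.logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

.ac_p_scalar <- function(x, y, N1, N2, alternative) {
  lower <- exp(.logsumexp(.ac_log_kernel(0:y, x, N1, N2)))
  # upper tail summed directly (no 1 - lower cancellation): terms decay
  # geometrically past the mode r*(x+1)/(1) of the implied distribution
  r <- N2 / N1
  y_hi <- ceiling(max(y, r * (x + 1)) + 30 * sqrt(r * (x + 1) + 10) + 200)
  upper <- exp(.logsumexp(.ac_log_kernel(y:y_hi, x, N1, N2)))
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         less = lower,
         greater = upper)
}

#' Audic-Claverie p-value for a two-library count comparison
#'
#' Exact test of whether a tag observed `x` times in a library of size
#' `N1` and `y` times in a library of size `N2` is sampled from the same
#' underlying abundance. The conditional distribution of `y` given `x`
#' has kernel `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`;
#' the two-sided p-value doubles the smaller cumulative tail (capped at
#' 1). Computation is in log space via `lgamma` with direct summation of
#' both tails, so small p-values carry full relative precision.
#'
#' @param x,y Tag counts in the two libraries, >= 0 (vectorized).
#' @param N1,N2 Library sizes, > 0.
#' @param alternative `"two.sided"` (doubled smaller tail, the default),
#'   `"less"` (lower tail) or `"greater"` (upper tail).
#' @return p-value(s) in (0, 1].
#' @examples
#' audic_claverie_p(50, 50, 1e6, 1e6)  # symmetry point: 1
#' audic_claverie_p(20, 80, 1e6, 1e6)
#' @export
audic_claverie_p <- function(x, y, N1, N2,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  check_flag(all(x >= 0) && all(y >= 0), "negative counts")
  check_flag(all(N1 > 0) && all(N2 > 0), "library sizes must be > 0")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i)
    .ac_p_scalar(x[i], y[i], N1[i], N2[i], alternative), 0)
}

#' Signed fold change between two expression values
#'
#' Ratio convention of drought-response tables: `r = treated/control`
#' reported as `r` when `r >= 1` and as `-1/r` otherwise, so that
#' `|FC| >= 1` always and the sign encodes the direction (negative =
#' down-regulated in the treated condition). Report-time rounding is
#' half-up to two decimals; this function returns full precision.
#'
#' @param tpm_treated,tpm_control Expression values (any common unit).
#' @return Signed fold change; `Inf`/`-Inf` sentinels when exactly one
#'   input is zero, `NA` when both are zero (flagged, undefined).
#' @examples
#' signed_fold_change(95.07, 38.57)  # 2.46 after rounding
#' signed_fold_change(45.43, 95.28)  # -2.10 after rounding
#' @export
signed_fold_change <- function(tpm_treated, tpm_control) {
  n <- max(length(tpm_treated), length(tpm_control))
  t <- rep_len(tpm_treated, n); c0 <- rep_len(tpm_control, n)
  out <- rep(NA_real_, n)
  both0 <- t == 0 & c0 == 0
  up <- !both0 & c0 == 0
  down <- !both0 & t == 0
  ok <- !both0 & !up & !down
  out[up] <- Inf
  out[down] <- -Inf
  r <- t[ok] / c0[ok]
  out[ok] <- ifelse(r >= 1, r, -1 / r)
  out
}

#' Call differential expression between two libraries
#'
#' For each record computes both TPMs, the signed fold change and the
#' Audic-Claverie p-value, and applies the significance filter
#' `|FC| > fc_min` and `p < alpha` (both strict, so a fold change of
#' exactly 2.00 is not called). Records with an infinite fold-change
#' sentinel (one count zero) are never called significant under the
#' default settings because the fold-change filter requires a finite
#' value; setting `pseudo_tpm > 0` instead floors zero TPMs at that
#' value before forming the ratio.
#'
#' @param records Data frame with columns `name`, `count_treated`,
#'   `count_control`.
#' @param N_treated,N_control Library sizes of the two libraries.
#' @param fc_min Minimum |fold change| (strict).
#' @param alpha Significance level (strict).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; the default `"none"` mirrors the per-miRNA
#'   p < 0.05 convention of two-library count studies.
#' @param pseudo_tpm Optional floor for zero TPMs (default off).
#' @return `records` with added columns `tpm_treated`, `tpm_control`,
#'   `fc`, `p`, `significant`.
#' @export
call_differential <- function(records, N_treated, N_control, fc_min = 2,
                              alpha = 0.05, p_adjust = "none",
                              pseudo_tpm = 0) {
  stopifnot(all(c("name", "count_treated", "count_control") %in%
                  names(records)))
  tt <- tpm(records$count_treated, N_treated)
  tc <- tpm(records$count_control, N_control)
  if (pseudo_tpm > 0) {
    tt <- pmax(tt, pseudo_tpm)
    tc <- pmax(tc, pseudo_tpm)
  }
  records$tpm_treated <- tt
  records$tpm_control <- tc
  records$fc <- signed_fold_change(tt, tc)
  records$p <- audic_claverie_p(records$count_treated,
                                records$count_control,
                                N_treated, N_control)
  padj <- p.adjust(records$p, method = p_adjust)
  records$significant <- is.finite(records$fc) &
    abs(records$fc) > fc_min & padj < alpha
  records
}
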