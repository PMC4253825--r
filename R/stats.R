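# Significance tests for candidate CNAs and the purity/ploidy-aware
# detection-limit filter.

#' Fixed variance test for a segment
#'
#' Standardized values `X_i = log(NRC_final_i) / sigma_i_sample` of a
#' copy-neutral segment are N(0, 1), so their mean is N(0, 1/n) and
#' `|mean(X)|` is half-normal. Two-sided P-value:
#' `P = 2 * (1 - pnorm(|mean(X)| * sqrt(n)))`.
#'
#' @param x standardized values of the segment's amplicons.
#' @return P-value in (0, 1].
#' @export
fixed_variance_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("empty segment: no standardized values")
  2 * pnorm(-abs(mean(x)) * sqrt(n))
}

#' One-sample t-test for a segment
#'
#' Tests the mean of the standardized values against 0 with the sample
#' standard deviation (n - 1 df). Because the sd is estimated rather than
#' fixed, this is usually more conservative than [fixed_variance_test()].
#' Undefined for n < 2 or zero sample sd; returns `NA` so the segment fails
#' the significance filter by convention.
#'
#' @param x standardized values of the segment's amplicons.
#' @return P-value, or `NA_real_` when undefined.
#' @export
t_test_segment <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || sd(x) == 0) return(NA_real_)
  t.test(x, mu = 0)$p.value
}

#' Expected copy ratio under a purity/ploidy model
#'
#' A CNA of `l` copies (gained or lost) carried by a fraction `c` of cells
#' in a tumor of ploidy `P` has expected normalized read count
#' `(1 - c) + c * (1 +/- l / P)`. As `c` falls or `P` rises this approaches
#' 1 and the CNA becomes undetectable.
#'
#' @param c fraction of cells carrying the CNA, in `[0, 1]`.
#' @param l copies gained or lost, >= 1.
#' @param ploidy tumor ploidy `P`, >= 1.
#' @param direction `"gain"` or `"loss"`.
#' @return Expected linear ratio (1 = neutral).
#' @export
expected_nrc <- function(c, l = 1, ploidy = 2, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(all(c >= 0 & c <= 1), all(l >= 1), all(ploidy >= 1))
  if (direction == "loss" && any(l > ploidy))
    stop("cannot lose more copies than the ploidy")
  sgn <- if (direction == "gain") 1 else -1
  (1 - c) + c * (1 + sgn * l / ploidy)
}

#' Minimum detectable cell fraction for the ratio-band filter
#'
#' Solves `expected_nrc(c) = band boundary` for `c`: CNAs carried by fewer
#' cells fall inside the filter band and are discarded. For a one-copy gain
#' the solution is `c = (boundary - 1) * P / l`.
#'
#' @param ploidy tumor ploidy.
#' @param l copies changed (default 1).
#' @param boundary filter band boundary (default 1.125, the upper edge of
#'   the default band).
#' @return Minimum fraction `c` in `[0, 1]`.
#' @export
min_detectable_fraction <- function(ploidy, l = 1, boundary = 1.125) {
  abs(boundary - 1) * ploidy / l
}

#' Weighted geometric mean of linear ratios
#'
#' `exp` of the weighted mean of the logs, weights `1/sigma_i^2`; zero or
#' negative ratios are excluded (masked amplicons).
#'
#' @param ratio linear per-amplicon ratios.
#' @param w weights.
#' @return Scalar weighted geometric mean.
#' @export
weighted_geo_mean <- function(ratio, w) {
  use <- is.finite(ratio) & ratio > 0 & is.finite(w)
  exp(sum(w[use] * log(ratio[use])) / sum(w[use]))
}

#' Apply the significance and purity-band filters to candidate CNAs
#'
#' A candidate survives iff its fixed variance test P and t-test P are both
#' below `p_threshold` AND its weighted geometric mean of linear NRCs lies
#' outside `ratio_band`. Failing candidates are demoted to neutral (kept in
#' the table with a reason flag) so gene tables always cover the panel.
#'
#' @param calls data.frame with columns `status`, `p_fixed`, `p_t`,
#'   `geo_mean` (one row per candidate segment or gene).
#' @param p_threshold significance threshold (default 0.01).
#' @param ratio_band closed band of undetectable ratios
#'   (default `c(0.875, 1.125)`).
#' @return `calls` with `status` demoted where filtered and a `filter`
#'   column: `"pass"`, `"significance"`, `"purity_band"` or `"neutral"`.
#' @export
filter_candidates <- function(calls, p_threshold = 0.01,
                              ratio_band = c(0.875, 1.125)) {
  stopifnot(all(c("status", "p_fixed", "p_t", "geo_mean") %in% names(calls)))
  flag <- rep("neutral", nrow(calls))
  cand <- calls$status != "neutral"
  sig_ok <- !is.na(calls$p_fixed) & !is.na(calls$p_t) &
    calls$p_fixed < p_threshold & calls$p_t < p_threshold
  in_band <- calls$geo_mean >= ratio_band[1] & calls$geo_mean <= ratio_band[2]
  flag[cand & !sig_ok] <- "significance"
  flag[cand & sig_ok & in_band] <- "purity_band"
  flag[cand & sig_ok & !in_band] <- "pass"
  calls$filter <- flag
  calls$status[cand & flag != "pass"] <- "neutral"
  calls
}
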