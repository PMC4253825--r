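# Weighted segmentation of log-ratio profiles, zero-level detection by
# mixture clustering of segment means, calibration of the per-sample noise
# scale, copy-number estimation, gene-aware breakpoint readjustment and
# per-amplicon outlier calls.

# weighted mean and its standard error for one segment; weights 1/sigma^2
seg_stats <- function(x, w) {
  n <- length(x)
  m <- sum(w * x) / sum(w)
  if (n == 1) return(c(wmean = m, sem = sqrt(1 / sum(w))))
  s2 <- sum(w * (x - m)^2) / (n - 1)          # unit-free scale factor
  c(wmean = m, sem = sqrt(max(s2, 1e-12) / sum(w)))
}

# recursive binary segmentation of positions lo..hi (indices into x/w);
# returns sorted vector of first-positions of segments
split_recursive <- function(x, w, lo, hi, alpha, nperm, minseg) {
  n <- hi - lo + 1L
  if (n < 2L * minseg) return(lo)
  sp <- cbs_split_cpp(x[lo:hi], w[lo:hi], nperm, alpha, minseg, 0L)
  if (is.na(sp$stat) || sp$p > alpha) return(lo)
  i <- lo + sp$i - 1L   # arc is positions i..j (inclusive)
  j <- lo + sp$j - 1L
  starts <- lo
  if (i > lo) starts <- c(starts, split_recursive(x, w, lo, i - 1L,
                                                  alpha, nperm, minseg), i)
  starts <- c(starts, split_recursive(x, w, i, j, alpha, nperm, minseg))
  if (j < hi) starts <- c(starts, j + 1L,
                          split_recursive(x, w, j + 1L, hi,
                                          alpha, nperm, minseg))
  sort(unique(starts))
}

#' Segment a log-ratio profile by weighted CBS
#'
#' Per-chromosome circular binary segmentation on the weighted CUSUM
#' statistic, amplicon weights `w = 1/sigma_i^2` so that noisy amplicons
#' cannot seed breakpoints. A candidate breakpoint pair is accepted when its
#' max-shift statistic beats `alpha` of `nperm` joint permutations of the
#' (value, weight) pairs; splitting recurses until no segment can be split.
#'
#' @param profile a `ratio_profile` from [regress_on_baseline()].
#' @param sigma_i per-amplicon standard deviations (from [fit_sigma()]).
#' @param alpha permutation acceptance level (default 0.01).
#' @param nperm permutations per split test (default 1000).
#' @param min_seg minimum amplicons per segment (default 2).
#' @return A `segments` data.frame: `chrom`, `first_id`, `last_id`, `n`,
#'   `wmean`, `sem`, plus attribute `amplicon_segment` mapping each unmasked
#'   amplicon id to its segment row.
#' @export
segment_profile <- function(profile, sigma_i, alpha = 0.01, nperm = 1000,
                            min_seg = 2) {
  use <- which(profile$mask & is.finite(profile$log_ratio) &
                 is.finite(sigma_i) & sigma_i > 0)
  if (!length(use)) stop("no usable amplicons to segment")
  chrom <- profile$panel$chrom[use]
  x <- profile$log_ratio[use]
  w <- 1 / sigma_i[use]^2
  seg_of <- integer(length(use))
  out <- list()
  sid <- 0L
  for (ch in unique(chrom)) {
    pos <- which(chrom == ch)
    if (length(pos) < 2L * min_seg) {
      starts_rel <- 1L
    } else {
      starts_rel <- split_recursive(x[pos], w[pos], 1L, length(pos),
                                    alpha, nperm, min_seg)
    }
    ends_rel <- c(starts_rel[-1] - 1L, length(pos))
    for (s in seq_along(starts_rel)) {
      sid <- sid + 1L
      idx <- pos[starts_rel[s]:ends_rel[s]]
      seg_of[idx] <- sid
      st <- seg_stats(x[idx], w[idx])
      out[[sid]] <- data.frame(chrom = ch,
                               first_id = profile$panel$id[use[idx[1]]],
                               last_id = profile$panel$id[use[idx[length(idx)]]],
                               n = length(idx), wmean = st[["wmean"]],
                               sem = st[["sem"]], stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, out)
  segs$segment <- seq_len(nrow(segs))
  amap <- data.frame(id = profile$panel$id[use], segment = seg_of)
  attr(segs, "amplicon_segment") <- amap
  class(segs) <- c("cna_segments", "data.frame")
  segs
}

#' Locate the copy-neutral (zero) level among segment means
#'
#' Segment means should cluster at integer-copy levels. Each segment's
#' weighted mean is resampled `m` times with Gaussian noise of sd equal to
#' its standard error (a sampling version of Parzen-window smoothing), a
#' 1-D equal-variance Gaussian mixture with 1..9 components is selected by
#' BIC (mclust), and the component with the maximum density peak is declared
#' neutral; ties go to the component closest to 0. Segments whose mean is
#' classified into that component are copy-neutral.
#'
#' @param segments a `cna_segments` data.frame.
#' @param m resampling draws per segment (default 50).
#' @param max_components maximum mixture size (default 9).
#' @param seed optional integer seed for the resampling draws.
#' @return List with `zero_level` (numeric), `neutral` (logical per
#'   segment), `cluster` (component index per segment), `fit` (the mclust
#'   model or NULL).
#' @export
find_zero_level <- function(segments, m = 50, max_components = 9,
                            seed = NULL) {
  stopifnot(nrow(segments) >= 1)
  if (nrow(segments) == 1)
    return(list(zero_level = segments$wmean[1], neutral = TRUE,
                cluster = 1L, fit = NULL))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  draws <- unlist(lapply(seq_len(nrow(segments)), function(i)
    rnorm(m, segments$wmean[i], segments$sem[i])))
  G <- seq_len(min(max_components, nrow(segments)))
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- suppressWarnings(
    mclust::Mclust(draws, G = G, modelNames = "E", verbose = FALSE))
  if (is.null(fit)) {   # degenerate draws: fall back to densest wmean
    zl <- segments$wmean[which.max(segments$n)]
    return(list(zero_level = zl,
                neutral = abs(segments$wmean - zl) < 1e-8,
                cluster = rep(1L, nrow(segments)), fit = NULL))
  }
  pro <- fit$parameters$pro
  mu <- unname(fit$parameters$mean)
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, fit$G)
  # the mixture can place duplicate components on one level; collapse
  # means closer than half the (common) component sd into one level before
  # ranking by density -- true copy levels sit several sds apart
  tol <- max(1e-6, 0.5 * sqrt(min(fit$parameters$variance$sigmasq)))
  ord <- order(mu)
  lvl <- integer(fit$G)
  lvl[ord] <- cumsum(c(1L, diff(mu[ord]) > tol))
  mix_dens <- function(x) sum(pro * stats::dnorm(x, mu, sig))
  lvl_mean <- vapply(split(seq_len(fit$G), lvl), function(k)
    sum(pro[k] * mu[k]) / sum(pro[k]), numeric(1))
  lvl_dens <- vapply(lvl_mean, mix_dens, numeric(1))
  tied <- which(lvl_dens >= max(lvl_dens) * (1 - 1e-6))
  neutral_lvl <- tied[which.min(abs(lvl_mean[tied]))]
  cl <- predict(fit, newdata = segments$wmean)$classification
  list(zero_level = unname(lvl_mean[neutral_lvl]),
       neutral = lvl[cl] == neutral_lvl, cluster = as.integer(cl),
       fit = fit)
}

#' Center a profile on the zero level and calibrate its noise scale
#'
#' Subtracts the zero level from all log ratios and segment means, then
#' estimates the per-sample scale `sigma_sample` as the standard deviation
#' of `log_ratio / sigma_i` over copy-neutral amplicons, giving calibrated
#' per-amplicon sds `sigma_i_sample = sigma_sample * sigma_i`. Segment
#' statuses are set relative to 0: neutral for the zero cluster, else
#' gain/loss by the sign of the centered mean.
#'
#' @param profile a `ratio_profile`.
#' @param segments a `cna_segments` data.frame from [segment_profile()].
#' @param zero the result of [find_zero_level()].
#' @param sigma_i per-amplicon sds from the baseline.
#' @return A `calibrated_profile`: list with centered `log_ratio`,
#'   `segments` (with `status`), `sigma_sample`, `sigma_i_sample`,
#'   `zero_level`, `mask`, `panel`, `sample`.
#' @export
calibrate <- function(profile, segments, zero, sigma_i) {
  amap <- attr(segments, "amplicon_segment")
  lr <- profile$log_ratio - zero$zero_level
  segments$wmean <- segments$wmean - zero$zero_level
  segments$status <- ifelse(zero$neutral, "neutral",
                            ifelse(segments$wmean > 0, "gain", "loss"))
  segments$cluster <- zero$cluster
  neutral_ids <- amap$id[zero$neutral[amap$segment]]
  if (!length(neutral_ids)) stop("zero level undeterminable: no neutral amplicons")
  z <- lr[neutral_ids] / sigma_i[neutral_ids]
  sigma_sample <- sd(z, na.rm = TRUE)
  if (!is.finite(sigma_sample) || sigma_sample <= 0)
    sigma_sample <- 1e-6
  structure(list(sample = profile$sample, log_ratio = lr,
                 segments = segments, zero_level = zero$zero_level,
                 sigma_sample = sigma_sample,
                 sigma_i_sample = sigma_sample * sigma_i,
                 mask = profile$mask, panel = profile$panel),
            class = "calibrated_profile")
}

#' Integer copy-number estimate from a linear ratio
#'
#' Inverts the expected-ratio relation under the stated ploidy: a ratio of
#' 1.5 in a diploid genome is 3 copies.
#'
#' @param ratio linear (not log) mean ratio, > 0.
#' @param ploidy assumed ploidy (default 2).
#' @return Integer copies (vectorised).
#' @export
estimate_copies <- function(ratio, ploidy = 2) {
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("ratio must be positive to estimate copies")
  as.integer(round(ploidy * ratio))
}

#' Move mis-positioned intragenic breakpoints to gene boundaries
#'
#' When a breakpoint splits a gene, either a real chromosomal break falls
#' inside the gene or noise shifted the breakpoint a few amplicons from the
#' true gene boundary. For each adjoining segment mean, a one-sample t-test
#' asks whether that single mean explains all the gene's log ratios; if the
#' best (largest) P exceeds `alpha` the whole gene is reassigned to that
#' segment, otherwise the intragenic break is kept. Genes with more
#' amplicons reassign more reliably.
#'
#' @param calibrated a `calibrated_profile`.
#' @param alpha rejection threshold for "one mean explains the gene"
#'   (default 0.01).
#' @return The `calibrated_profile` with segments rebuilt after
#'   reassignment.
#' @export
readjust_gene_breakpoints <- function(calibrated, alpha = 0.01) {
  segs <- calibrated$segments
  amap <- attr(segs, "amplicon_segment")
  panel <- calibrated$panel
  gr <- gene_ranges(panel)
  seg_of <- setNames(amap$segment, amap$id)
  for (g in seq_len(nrow(gr))) {
    ids <- as.character(gr$first_id[g]:gr$last_id[g])
    ids <- ids[ids %in% names(seg_of)]
    if (length(ids) < 2) next
    in_segs <- unique(seg_of[ids])
    if (length(in_segs) < 2) next
    y <- calibrated$log_ratio[as.integer(ids)]
    p <- vapply(in_segs, function(s) {
      mu <- segs$wmean[segs$segment == s]
      if (sd(y) == 0) return(if (isTRUE(all.equal(y[1], mu))) 1 else 0)
      t.test(y, mu = mu)$p.value
    }, numeric(1))
    if (max(p) > alpha)
      seg_of[ids] <- in_segs[which.max(p)]
  }
  calibrated$segments <- rebuild_segments(seg_of, calibrated)
  calibrated
}

# rebuild segment table from a per-amplicon assignment (runs of equal
# assignment within a chromosome), keeping each assignment's status
rebuild_segments <- function(seg_of, calibrated) {
  old <- calibrated$segments
  ids <- as.integer(names(seg_of))
  ord <- order(match(ids, calibrated$panel$id))
  ids <- ids[ord]; seg_of <- seg_of[ord]
  chrom <- calibrated$panel$chrom[match(ids, calibrated$panel$id)]
  r <- rle(paste(chrom, seg_of, sep = "\r"))
  last <- cumsum(r$lengths); first <- last - r$lengths + 1L
  sigma_i_rel <- calibrated$sigma_i_sample / calibrated$sigma_sample
  out <- lapply(seq_along(first), function(k) {
    idx <- ids[first[k]:last[k]]
    w <- 1 / sigma_i_rel[idx]^2
    st <- seg_stats(calibrated$log_ratio[idx], w)
    o <- old[old$segment == seg_of[first[k]], , drop = FALSE]
    data.frame(chrom = chrom[first[k]], first_id = idx[1],
               last_id = idx[length(idx)], n = length(idx),
               wmean = st[["wmean"]], sem = st[["sem"]],
               status = o$status, cluster = o$cluster,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, out)
  segs$segment <- seq_len(nrow(segs))
  amap <- data.frame(id = ids,
                     segment = rep(segs$segment, r$lengths))
  attr(segs, "amplicon_segment") <- amap
  class(segs) <- c("cna_segments", "data.frame")
  segs
}

#' Per-amplicon outlier tests
#'
#' One-amplicon events are not promoted to CNA calls, but each amplicon is
#' tested against its segment: two-sided P under
#' `Normal(wm_seg, sigma_i_sample)`, Benjamini-Hochberg adjusted across all
#' unmasked amplicons of the sample.
#'
#' @param calibrated a `calibrated_profile`.
#' @param q_threshold outlier flag threshold on the BH q-value
#'   (default 0.05).
#' @return data.frame: `id`, `segment`, `log_ratio`, `p`, `q`, `outlier`.
#' @export
call_outlier_amplicons <- function(calibrated, q_threshold = 0.05) {
  segs <- calibrated$segments
  amap <- attr(segs, "amplicon_segment")
  wm <- segs$wmean[match(amap$segment, segs$segment)]
  z <- (calibrated$log_ratio[amap$id] - wm) /
    calibrated$sigma_i_sample[amap$id]
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  data.frame(id = amap$id, segment = amap$segment,
             log_ratio = calibrated$log_ratio[amap$id],
             p = p, q = q, outlier = q < q_threshold)
}
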