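# Two-phase orchestration: (1) build and serialize the control baseline;
# (2) process each tumor sample through normalization, baseline regression,
# segmentation, zero-level calibration, gene readjustment, statistical
# filtering and outlier calls. Both phases accept a count table so the full
# pipeline runs without alignment files; BAM/SAM input is counted first.

#' Control phase: counts to serialized baseline
#'
#' Normalizes every control, infers genders from chrX dosage, doubles male
#' chrX counts, re-normalizes, builds the PCA baseline and fits the
#' per-amplicon noise model.
#'
#' @param cm a [count_matrix()] of control samples (>= 2).
#' @param n_pcs baseline components (default `min(3, n - 1)`).
#' @param loess_span LOESS span for GC/length detrending.
#' @param min_mean_nrc panel-wide dead-amplicon threshold.
#' @param gender_threshold single-cluster male cutoff on `M`.
#' @param out optional path: baseline TSV (+ `.json` sidecar) written there.
#' @return The fitted `cna_baseline`, with a `qc` attribute (gender calls,
#'   explained variance, masked amplicon count).
#' @export
run_control_phase <- function(cm, n_pcs = NULL, loess_span = 0.3,
                              min_mean_nrc = 0.01, gender_threshold = 0.9,
                              out = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2)
    stop("at least two control samples are necessary")
  norm1 <- lapply(cm$samples, function(s)
    normalize_sample(cm$counts[, s], cm$panel, span = loess_span,
                     sample = s))
  genders <- infer_gender(norm1, cm$panel, threshold = gender_threshold)
  cm2 <- apply_gender_correction(cm, genders)
  profiles <- lapply(cm2$samples, function(s)
    normalize_sample(cm2$counts[, s], cm2$panel, span = loess_span,
                     sample = s))
  baseline <- build_baseline(profiles, n_pcs = n_pcs,
                             min_mean_nrc = min_mean_nrc)
  ratios <- lapply(profiles, regress_on_baseline, baseline = baseline)
  baseline <- fit_sigma(ratios, baseline)
  attr(baseline, "qc") <- list(genders = genders,
                               explained_variance = baseline$explained_variance,
                               n_masked = sum(!baseline$mask))
  if (!is.null(out)) write_baseline(baseline, out)
  baseline
}

#' Tumor phase: counts to CNA calls
#'
#' Normalizes the tumor, regresses it on the baseline, segments with
#' weighted CBS, locates the zero level, calibrates the sample noise scale,
#' readjusts intragenic breakpoints, runs the fixed-variance and t-tests
#' with the purity-band filter, and reports per-amplicon outliers.
#'
#' @param counts raw count column for one tumor sample.
#' @param baseline a fitted `cna_baseline`.
#' @param panel optional [amplicon_panel()] the tumor was counted on;
#'   verified against the baseline's panel hash (a mismatch is an error).
#' @param sample sample name.
#' @param loess_span LOESS span for GC/length detrending.
#' @param alpha CBS permutation acceptance level.
#' @param nperm CBS permutations.
#' @param m_draws resampling draws per segment for zero-level clustering.
#' @param p_threshold CNA significance threshold.
#' @param ratio_band undetectable-ratio band.
#' @param ploidy assumed ploidy for copy-number estimates.
#' @param seed seed for the zero-level resampling.
#' @param outdir optional directory: segment, gene and amplicon TSVs
#'   written there.
#' @return A `cna_call_set`: list with `sample`, `segments`, `genes`,
#'   `amplicons`, `calibrated`, `zero_level`, `sigma_sample`.
#' @export
run_tumor_phase <- function(counts, baseline, panel = NULL,
                            sample = "tumor",
                            loess_span = 0.3, alpha = 0.01, nperm = 1000,
                            m_draws = 50, p_threshold = 0.01,
                            ratio_band = c(0.875, 1.125), ploidy = 2,
                            seed = NULL, outdir = NULL) {
  if (!is.null(panel) &&
      !identical(panel_hash(panel), baseline$panel_hash))
    stop("panel mismatch: tumor was counted on a different panel ",
         "than the baseline")
  if (length(counts) != nrow(baseline$panel))
    stop("panel mismatch: count column length differs from the baseline ",
         "panel")
  profile <- normalize_sample(counts, baseline$panel, span = loess_span,
                              sample = sample)
  ratio <- regress_on_baseline(profile, baseline)
  segs <- segment_profile(ratio, baseline$sigma_i, alpha = alpha,
                          nperm = nperm)
  zero <- find_zero_level(segs, m = m_draws, seed = seed)
  cal <- calibrate(ratio, segs, zero, baseline$sigma_i)
  cal <- readjust_gene_breakpoints(cal, alpha = p_threshold)
  seg_calls <- test_segments(cal, ploidy = ploidy)
  seg_calls <- filter_candidates(seg_calls, p_threshold = p_threshold,
                                 ratio_band = ratio_band)
  genes <- summarize_genes(cal, seg_calls, ploidy = ploidy)
  outliers <- call_outlier_amplicons(cal)
  res <- structure(list(sample = sample, segments = seg_calls,
                        genes = genes, amplicons = outliers,
                        calibrated = cal, zero_level = cal$zero_level,
                        sigma_sample = cal$sigma_sample),
                   class = "cna_call_set")
  if (!is.null(outdir)) write_call_set(res, outdir)
  res
}

# per-segment tests and summaries on a calibrated profile
test_segments <- function(cal, ploidy = 2) {
  segs <- cal$segments
  amap <- attr(segs, "amplicon_segment")
  out <- segs
  out$ratio <- exp(out$wmean)
  out$copies <- estimate_copies(out$ratio, ploidy)
  out$geo_mean <- NA_real_
  out$p_fixed <- NA_real_
  out$p_t <- NA_real_
  for (k in seq_len(nrow(out))) {
    ids <- amap$id[amap$segment == segs$segment[k]]
    x <- cal$log_ratio[ids] / cal$sigma_i_sample[ids]
    w <- 1 / (cal$sigma_i_sample[ids] / cal$sigma_sample)^2
    out$geo_mean[k] <- weighted_geo_mean(exp(cal$log_ratio[ids]), w)
    out$p_fixed[k] <- fixed_variance_test(x)
    out$p_t[k] <- t_test_segment(x)
  }
  out
}

# gene-level summary: a gene takes the status of the segment(s) covering it
summarize_genes <- function(cal, seg_calls, ploidy = 2) {
  amap <- attr(cal$segments, "amplicon_segment")
  gr <- gene_ranges(cal$panel)
  sigma_rel <- cal$sigma_i_sample / cal$sigma_sample
  rows <- lapply(seq_len(nrow(gr)), function(g) {
    ids <- intersect(gr$first_id[g]:gr$last_id[g], amap$id)
    if (!length(ids))
      return(data.frame(gene = gr$gene[g], chrom = gr$chrom[g],
                        n_amplicons = 0L, status = NA_character_,
                        log_ratio = NA_real_, ratio = NA_real_,
                        copies = NA_integer_, filter = NA_character_,
                        stringsAsFactors = FALSE))
    segids <- unique(amap$segment[amap$id %in% ids])
    sc <- seg_calls[seg_calls$segment %in% segids, , drop = FALSE]
    # dominant segment: the one covering most of the gene's amplicons
    cover <- vapply(segids, function(s)
      sum(amap$segment == s & amap$id %in% ids), integer(1))
    dom <- sc[match(segids[which.max(cover)], sc$segment), ]
    w <- 1 / sigma_rel[ids]^2
    lr <- sum(w * cal$log_ratio[ids]) / sum(w)
    data.frame(gene = gr$gene[g], chrom = gr$chrom[g],
               n_amplicons = length(ids), status = dom$status,
               log_ratio = lr, ratio = exp(lr),
               copies = estimate_copies(exp(lr), ploidy),
               filter = dom$filter, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the output tables of a tumor run
#'
#' Segment, gene and amplicon TSVs (`<sample>.segments.tsv` etc.) with a
#' provenance header line (package version).
#'
#' @param res a `cna_call_set`.
#' @param outdir output directory (created if missing).
#' @export
write_call_set <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# ampliCNA ", as.character(packageVersion("ampliCNA")),
                " sample=", res$sample,
                " zero_level=", signif(res$zero_level, 6),
                " sigma_sample=", signif(res$sigma_sample, 6))
  wt <- function(df, name) {
    p <- file.path(outdir, paste0(res$sample, ".", name, ".tsv"))
    con <- file(p, "w"); on.exit(close(con))
    writeLines(hdr, con)
    df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(as.data.frame(res$segments), "segments")
  wt(res$genes, "genes")
  wt(res$amplicons, "amplicons")
  invisible(outdir)
}

#' Plot a per-sample copy-ratio profile
#'
#' Base-graphics profile of per-amplicon log ratios colored by segment
#' status (gain red, loss blue, neutral grey), with segment means overlaid.
#'
#' @param x a `cna_call_set`.
#' @param ... passed to `plot()`.
#' @export
plot.cna_call_set <- function(x, ...) {
  cal <- x$calibrated
  amap <- attr(cal$segments, "amplicon_segment")
  segs <- x$segments
  st <- segs$status[match(amap$segment, segs$segment)]
  col <- c(gain = "firebrick", loss = "steelblue", neutral = "grey50")[st]
  plot(amap$id, cal$log_ratio[amap$id], col = col, pch = 16, cex = 0.5,
       xlab = "amplicon", ylab = "log ratio",
       main = paste0(x$sample, " (zero level ",
                     signif(x$zero_level, 3), ")"), ...)
  graphics::segments(segs$first_id, segs$wmean, segs$last_id, segs$wmean,
                     lwd = 2, col = "black")
  abline(h = 0, lty = 3)
  invisible(x)
}
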