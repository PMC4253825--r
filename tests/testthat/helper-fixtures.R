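# Shared fixture builders. All data are generated in code; panels are kept
# small so the whole suite stays fast.

# simple panel on one or more chromosomes, evenly spaced amplicons
toy_panel <- function(n = 8, chrom = "chr1", gene = NULL, len = 100,
                      gap = 50, gc = 0.5) {
  if (is.null(gene)) gene <- paste0("G", rep(seq_len(max(1, n %/% 4)),
                                             each = 4, length.out = n))
  start <- seq(0, by = len + gap, length.out = n)
  amplicon_panel(rep_len(chrom, n), start, start + len, gene,
                 gc = rep_len(gc, n))
}

# hand-built normalized_profile (bypasses counts) for baseline-module tests
fake_profile <- function(nrc_len, panel, sample = "s",
                         nrc_lib = nrc_len, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(nrc_len) & nrc_len > 0
  structure(list(sample = sample, nrc_lib = nrc_lib, nrc_gc = nrc_len,
                 nrc_len = nrc_len, mask = mask, panel = panel),
            class = "normalized_profile")
}

# hand-built ratio_profile for segmentation tests
fake_ratio <- function(log_ratio, panel, sample = "s", mask = NULL) {
  if (is.null(mask)) mask <- is.finite(log_ratio)
  structure(list(sample = sample, log_ratio = log_ratio,
                 fitted = rep(0, length(log_ratio)), mask = mask,
                 panel = panel),
            class = "ratio_profile")
}

# default small simulated cohort used by several files
small_cohort <- function(n_genes = 20, cna = NULL, n_tumors = 1, seed = 42,
                         ...) {
  cfg <- sim_config(n_genes = n_genes, cna_spec = cna, ...)
  simulate_cohort(cfg, n_tumors = n_tumors, seed = seed)
}

# subset a count_matrix to the control columns
controls_only <- function(sim) {
  cm <- sim$counts
  cm$counts <- cm$counts[, sim$control_names, drop = FALSE]
  cm$samples <- sim$control_names
  cm$total_reads <- cm$total_reads[sim$control_names]
  cm
}

# brute-force maximum-overlap assignment used as oracle for assign_reads
oracle_assign <- function(chrom, start, end, panel) {
  vapply(seq_along(start), function(r) {
    ov <- ifelse(panel$chrom == chrom[r],
                 pmin(end[r], panel$end) - pmax(start[r], panel$start), 0)
    ov[ov < 0] <- 0
    if (all(ov == 0)) return(NA_integer_)
    best <- which(ov == max(ov))
    best <- best[order(panel$start[best], panel$id[best])][1]
    panel$id[best]
  }, integer(1))
}

# brute-force reciprocal-overlap merging to a fixed point (pairwise oracle)
oracle_merge <- function(df, min_frac = 0.75) {
  repeat {
    n <- nrow(df)
    done <- TRUE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (df$chrom[i] != df$chrom[j]) next
        ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
        li <- df$end[i] - df$start[i]; lj <- df$end[j] - df$start[j]
        if (ov > min_frac * li && ov > min_frac * lj) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) return(df[order(df$chrom, df$start), c("chrom", "start", "end")])
  }
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}
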