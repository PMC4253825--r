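# Synthetic-data generator: amplicon panels, copy-neutral control cohorts
# and tumor samples with planted CNAs, emulating the biases the pipeline is
# built to remove — amplicon-specific PCR efficiency, GC and length biases,
# per-sample technology noise, male chrX dosage, and the purity/ploidy
# dilution of planted aberrations.

#' Simulation configuration
#'
#' Defaults are the study conditions used throughout the test-suite: a
#' 40-gene panel of 8 amplicons each, amplicon lengths 70-140 bp, GC
#' 0.3-0.7, lognormal per-amplicon PCR efficiency with log-sd 0.5,
#' unimodal GC bias `exp(-4 (gc - 0.5)^2)` and a decreasing length bias
#' `exp(-(len - 70) / 70)`, per-sample multiplicative noise with log-sd 0.1,
#' 15 diploid controls and a mean depth of 1000 reads per amplicon.
#'
#' @param n_genes genes in the panel.
#' @param amplicons_per_gene amplicons per gene.
#' @param gc_range,length_range uniform sampling ranges for GC fraction and
#'   amplicon length (bp).
#' @param efficiency_sd log-scale sd of the fixed per-amplicon PCR
#'   efficiency shared by every sample.
#' @param gc_bias_strength,length_bias_strength bias strengths `k` in the
#'   shapes above (0 disables a bias).
#' @param sample_noise_sd log-scale sd of the per-amplicon, per-sample
#'   multiplicative technology noise.
#' @param depth mean reads per amplicon (library size is
#'   `depth * n_amplicons`).
#' @param n_controls diploid controls in the cohort.
#' @param genders control genders, recycled (`"female"`/`"male"`); male
#'   samples halve chrX dosage.
#' @param chrx_genes how many genes to place on chrX (default 0).
#' @param ploidy tumor ploidy `P`.
#' @param cna_spec data.frame of planted CNAs: `gene`, `direction`
#'   (gain/loss), `l` (copies changed), `c` (cell fraction).
#' @param overdispersion_sd optional extra lognormal count noise (default 0
#'   = pure Poisson).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 40, amplicons_per_gene = 8,
                       gc_range = c(0.3, 0.7), length_range = c(70, 140),
                       efficiency_sd = 0.5, gc_bias_strength = 4,
                       length_bias_strength = 1, sample_noise_sd = 0.1,
                       depth = 1000, n_controls = 15, genders = "female",
                       chrx_genes = 0, ploidy = 2, cna_spec = NULL,
                       overdispersion_sd = 0) {
  stopifnot(efficiency_sd >= 0, sample_noise_sd >= 0, depth > 0,
            overdispersion_sd >= 0, ploidy >= 1)
  if (!is.null(cna_spec))
    stopifnot(all(cna_spec$c >= 0 & cna_spec$c <= 1), all(cna_spec$l >= 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an amplicon panel
#'
#' Genes get contiguous runs of amplicons laid out on autosomes (about ten
#' genes per chromosome), with the last `chrx_genes` genes moved to chrX.
#' GC and length are sampled uniformly from the configured ranges.
#'
#' @param config a [sim_config()].
#' @return An [amplicon_panel()] plus attribute `efficiency`: the fixed
#'   per-amplicon PCR efficiency profile used by [simulate_counts()].
#' @export
simulate_panel <- function(config) {
  ng <- config$n_genes; na <- config$amplicons_per_gene
  n <- ng * na
  gene_chr <- paste0("chr", 1 + (seq_len(ng) - 1) %/% 10)
  if (config$chrx_genes > 0)
    gene_chr[seq(ng - config$chrx_genes + 1, ng)] <- "chrX"
  chrom <- rep(gene_chr, each = na)
  gene <- rep(sprintf("GENE%03d", seq_len(ng)), each = na)
  len <- round(runif(n, config$length_range[1], config$length_range[2]))
  # lay amplicons end to end with 200 bp gaps, restarting per chromosome
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1000, head(len[i], -1) + 200))
  }
  gc <- runif(n, config$gc_range[1], config$gc_range[2])
  panel <- amplicon_panel(chrom, start, start + len, gene, gc)
  attr(panel, "efficiency") <- exp(rnorm(n, 0, config$efficiency_sd))
  panel
}

# bias curves; strength 0 gives a flat curve
gc_bias_curve <- function(gc, k) exp(-k * (gc - 0.5)^2)
length_bias_curve <- function(len, k, len0 = 70) exp(-k * (len - len0) / len0)

#' Simulate one raw count column
#'
#' Per-amplicon Poisson counts with rate
#' `depth * efficiency * gc_bias * length_bias * copy_ratio * noise`;
#' male samples halve the chrX copy ratio.
#'
#' @param panel panel from [simulate_panel()] (carries the efficiency
#'   attribute).
#' @param config a [sim_config()].
#' @param copy_ratio per-amplicon true copy ratio (1 = neutral diploid).
#' @param gender `"female"` or `"male"`.
#' @return Integer count column.
#' @export
simulate_counts <- function(panel, config, copy_ratio = 1,
                            gender = "female") {
  n <- nrow(panel)
  copy_ratio <- rep_len(copy_ratio, n)
  stopifnot(all(copy_ratio > 0))
  eff <- attr(panel, "efficiency")
  if (is.null(eff)) eff <- rep(1, n)
  cr <- copy_ratio
  if (gender == "male") cr[panel$chrom %in% c("chrX", "X")] <-
      cr[panel$chrom %in% c("chrX", "X")] / 2
  noise <- exp(rnorm(n, 0, config$sample_noise_sd))
  if (config$overdispersion_sd > 0)
    noise <- noise * exp(rnorm(n, 0, config$overdispersion_sd))
  rate <- config$depth * eff * gc_bias_curve(panel$gc, config$gc_bias_strength) *
    length_bias_curve(panel$length, config$length_bias_strength) * cr * noise
  rpois(n, rate)
}

#' Simulate a control cohort plus tumor samples
#'
#' Controls are copy-neutral (chrX dosage per gender); each tumor applies
#' the planted CNAs of `config$cna_spec` through the purity model: a gene
#' carrying a CNA of `l` copies in a fraction `c` of cells has true ratio
#' [expected_nrc()] `(1-c) + c (1 +/- l/P)`.
#'
#' @param config a [sim_config()].
#' @param n_tumors tumor samples to draw (default 1; 0 for controls only).
#' @param seed optional integer seed (bit-for-bit reproducible).
#' @return List: `counts` (a [count_matrix()], controls then tumors),
#'   `panel`, `truth` (per-gene data.frame: `gene`, `status`, `l`, `c`,
#'   `expected_nrc`), `copy_ratio` (per-amplicon true tumor ratio),
#'   `control_names`, `tumor_names`, `genders`.
#' @export
simulate_cohort <- function(config, n_tumors = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- simulate_panel(config)
  genders <- rep_len(config$genders, config$n_controls)
  ctrl <- lapply(seq_len(config$n_controls), function(i)
    simulate_counts(panel, config, 1, genders[i]))
  truth <- data.frame(gene = sprintf("GENE%03d", seq_len(config$n_genes)),
                      status = "neutral", l = 0L, c = 0,
                      expected_nrc = 1, stringsAsFactors = FALSE)
  cr <- rep(1, nrow(panel))
  if (!is.null(config$cna_spec)) {
    for (i in seq_len(nrow(config$cna_spec))) {
      s <- config$cna_spec[i, ]
      en <- expected_nrc(s$c, s$l, config$ploidy, s$direction)
      j <- truth$gene == s$gene
      truth$status[j] <- s$direction
      truth$l[j] <- s$l; truth$c[j] <- s$c; truth$expected_nrc[j] <- en
      cr[panel$gene == s$gene] <- en
    }
  }
  tum <- lapply(seq_len(n_tumors), function(i)
    simulate_counts(panel, config, cr, "female"))
  counts <- do.call(cbind, c(ctrl, tum))
  cn <- c(sprintf("control%02d", seq_len(config$n_controls)),
          if (n_tumors > 0) sprintf("tumor%02d", seq_len(n_tumors)))
  colnames(counts) <- cn
  cm <- count_matrix(panel, counts)
  list(counts = cm, panel = panel, truth = truth, copy_ratio = cr,
       control_names = cn[seq_len(config$n_controls)],
       tumor_names = if (n_tumors > 0)
         cn[config$n_controls + seq_len(n_tumors)] else character(0),
       genders = genders)
}
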