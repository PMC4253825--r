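# Technology-specific normalization: PCA baseline over diploid controls,
# regression of samples on it, and the per-amplicon noise model
# sigma_i = f(PC1).
#
# PCA orientation: amplicons are observations and controls are variables,
# computed on column-centred log NRC_Len without variance scaling. This
# makes PC1 essentially the shared per-amplicon efficiency profile, which
# is why it tracks the cross-control mean almost perfectly.

#' Build the control baseline by PCA
#'
#' Stacks the controls' `log(NRC_Len)` into an amplicons x controls matrix,
#' masks amplicons unusable in any control or with cohort-mean NRC_Lib below
#' `min_mean_nrc`, and runs covariance PCA. By default `min(3, n - 1)`
#' components are kept; PC1's sign is fixed so that it correlates positively
#' with the per-amplicon mean profile.
#'
#' @param profiles list of >= 2 control `normalized_profile`s
#'   (gender-corrected counts).
#' @param n_pcs number of components to keep (default `min(3, n - 1)`).
#' @param min_mean_nrc panel-wide exclusion threshold on the cohort mean
#'   NRC_Lib (default 0.01); systematically dead amplicons carry no signal.
#' @return A `cna_baseline`: list with `pc_scores` (amplicons x k),
#'   `explained_variance`, `k`, `mask`, `control_names`, `mean_log_nrc`,
#'   `panel_hash`, `panel`; `sigma_i` is filled in by [fit_sigma()].
#' @export
build_baseline <- function(profiles, n_pcs = NULL, min_mean_nrc = 0.01) {
  n <- length(profiles)
  if (n < 2) stop("at least two control samples are necessary")
  panel <- profiles[[1]]$panel
  L <- vapply(profiles, function(p) log(p$nrc_len), numeric(nrow(panel)))
  colnames(L) <- vapply(profiles, function(p) p$sample, "")
  mask <- Reduce(`&`, lapply(profiles, `[[`, "mask"))
  mean_lib <- rowMeans(vapply(profiles, `[[`, numeric(nrow(panel)),
                              "nrc_lib"))
  mask <- mask & mean_lib >= min_mean_nrc & apply(is.finite(L), 1, all)
  k <- if (is.null(n_pcs)) min(3L, n - 1L) else as.integer(n_pcs)
  k <- min(k, n - 1L)
  pca <- prcomp(L[mask, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- matrix(NA_real_, nrow(panel), k,
                   dimnames = list(NULL, paste0("PC", seq_len(k))))
  sc <- pca$x[, seq_len(k), drop = FALSE]
  m <- rowMeans(L[mask, , drop = FALSE])
  if (cor(sc[, 1], m) < 0) sc[, 1] <- -sc[, 1]
  scores[mask, ] <- sc
  structure(list(pc_scores = scores, explained_variance = ev[seq_len(k)],
                 k = k, mask = mask, control_names = colnames(L),
                 mean_log_nrc = ifelse(mask, rowMeans(L), NA_real_),
                 sigma_i = NULL, panel = panel,
                 panel_hash = panel_hash(panel)),
            class = "cna_baseline")
}

# order-sensitive fingerprint of the panel coordinates
panel_hash <- function(panel) {
  s <- paste(panel$chrom, panel$start, panel$end, collapse = ";")
  # small rolling hash; no digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x-%d", h, nrow(panel))
}

#' Regress a sample on the baseline
#'
#' Ordinary least squares of the sample's `log(NRC_Len)` on the kept PC
#' score columns plus an intercept, over unmasked amplicons. The residuals
#' are the sample's copy-ratio profile: a global multiplicative shift of the
#' sample moves only the intercept, never the residuals.
#'
#' @param profile a `normalized_profile`.
#' @param baseline a `cna_baseline` built on the same panel.
#' @return A `ratio_profile`: list with `sample`, `log_ratio` (residuals,
#'   NA where masked), `fitted`, `mask`, `panel`.
#' @export
regress_on_baseline <- function(profile, baseline) {
  stopifnot(inherits(baseline, "cna_baseline"))
  if (!identical(panel_hash(profile$panel), baseline$panel_hash))
    stop("panel mismatch: sample was counted on a different panel ",
         "than the baseline")
  mask <- baseline$mask & profile$mask & is.finite(profile$nrc_len) &
    profile$nrc_len > 0
  y <- log(profile$nrc_len[mask])
  X <- baseline$pc_scores[mask, , drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient baseline design: degenerate control cohort")
  fit <- lm(y ~ X)
  lr <- rep(NA_real_, nrow(profile$panel))
  fv <- rep(NA_real_, nrow(profile$panel))
  lr[mask] <- residuals(fit)
  fv[mask] <- fitted(fit)
  structure(list(sample = profile$sample, log_ratio = lr, fitted = fv,
                 mask = mask, panel = profile$panel),
            class = "ratio_profile")
}

#' Model per-amplicon noise as a function of PC1
#'
#' Each control's residual profile is first rescaled to overall variance 1
#' (sample-to-sample noise levels differ). Pooled squared residuals are then
#' regressed on PC1 by LOESS (degree 2): higher-coverage amplicons (large
#' PC1) are less noisy. `sigma_i = sqrt(max(fit, floor))`.
#'
#' @param ratio_profiles list of control `ratio_profile`s from
#'   [regress_on_baseline()].
#' @param baseline the `cna_baseline`; updated in place.
#' @param span LOESS span (default 0.75; the trend in PC1 is broad).
#' @param floor variance floor (default 1e-3).
#' @return The baseline with `sigma_i` filled (NA where masked).
#' @export
fit_sigma <- function(ratio_profiles, baseline, span = 0.75, floor = 1e-3) {
  stopifnot(length(ratio_profiles) >= 2)
  R <- vapply(ratio_profiles, `[[`, numeric(nrow(baseline$panel)),
              "log_ratio")
  R <- apply(R, 2, function(r) r / sd(r, na.rm = TRUE))
  pc1 <- baseline$pc_scores[, 1]
  use <- which(baseline$mask & is.finite(pc1))
  x <- rep(pc1[use], ncol(R))
  y <- as.vector(R[use, ])
  ok <- is.finite(y)
  d <- data.frame(v = y[ok]^2, p = x[ok])
  # the trend in PC1 is broad: a capped, PC1-stratified subsample keeps the
  # fit well conditioned and fast on large pooled cohorts
  if (nrow(d) > 10000) {
    d <- d[order(d$p), , drop = FALSE]
    d <- d[unique(round(seq(1, nrow(d), length.out = 10000))), , drop = FALSE]
  }
  fit <- loess(v ~ p, data = d, span = span, degree = 2,
               family = "symmetric")
  xc <- pmin(pmax(pc1[use], min(d$p)), max(d$p))
  v <- predict(fit, newdata = data.frame(p = xc))
  sigma <- rep(NA_real_, nrow(baseline$panel))
  sigma[use] <- sqrt(pmax(v, floor))
  baseline$sigma_i <- sigma
  baseline
}

#' Serialize a baseline to TSV (+ JSON sidecar)
#'
#' The TSV holds per-amplicon scores, sigma and mask; the sidecar records
#' explained variance, control names, k and the panel hash, so tumors cannot
#' be normalized against a mismatched panel.
#'
#' @param baseline a `cna_baseline` (after [fit_sigma()]).
#' @param path output TSV path; sidecar written to `<path>.json`.
#' @export
write_baseline <- function(baseline, path) {
  df <- data.frame(id = baseline$panel$id, chrom = baseline$panel$chrom,
                   start = baseline$panel$start, end = baseline$panel$end,
                   gene = baseline$panel$gene, gc = baseline$panel$gc,
                   length = baseline$panel$length,
                   baseline$pc_scores,
                   mean_log_nrc = baseline$mean_log_nrc,
                   sigma_i = if (is.null(baseline$sigma_i)) NA_real_ else
                     baseline$sigma_i,
                   mask = baseline$mask, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = baseline$k,
               explained_variance = baseline$explained_variance,
               control_names = baseline$control_names,
               panel_hash = baseline$panel_hash)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dput(meta, file = paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a baseline written by [write_baseline()]
#' @param path TSV path (expects `<path>.json` sidecar alongside).
#' @return A `cna_baseline`.
#' @export
read_baseline <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  side <- paste0(path, ".json")
  meta <- if (requireNamespace("jsonlite", quietly = TRUE) &&
              file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else dget(side)
  panel <- amplicon_panel(df$chrom, df$start, df$end, df$gene, df$gc)
  pccols <- grep("^PC[0-9]+$", names(df), value = TRUE)
  structure(list(pc_scores = as.matrix(df[, pccols, drop = FALSE]),
                 explained_variance = meta$explained_variance,
                 k = meta$k, mask = as.logical(df$mask),
                 control_names = meta$control_names,
                 mean_log_nrc = df$mean_log_nrc,
                 sigma_i = df$sigma_i, panel = panel,
                 panel_hash = meta$panel_hash),
            class = "cna_baseline")
}
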