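# Library-specific normalization: library size, GC-content LOESS,
# amplicon-length LOESS; gender inference and chrX correction of controls.
#
# Corrections are fitted on the log scale and applied multiplicatively:
# the biases are multiplicative in count space, hence additive in log space,
# and downstream segmentation operates on log values anyway.

#' Library-size normalization
#'
#' Divides raw read counts (RRC) by the average per-amplicon count
#' `Avg = N / R`, where `N` is the library size and `R` the number of
#' amplicons. Under equal PCR efficiency the result is close to 1 everywhere.
#'
#' @param counts raw count column (one sample).
#' @param total_reads library size `N`; defaults to `sum(counts)`.
#' @return Numeric vector of NRC_Lib values.
#' @export
normalize_library_size <- function(counts, total_reads = sum(counts)) {
  if (total_reads <= 0) stop("empty library: total read count is zero")
  counts / (total_reads / length(counts))
}

#' Remove a smooth covariate trend by LOESS
#'
#' Fits `f(covariate)` to `log(values)` by local polynomial regression
#' (degree 2), then returns `exp(log(values) - f + mean(f))` so the
#' geometric mean over the fitted amplicons is preserved. Covariate values
#' outside the fitted support are corrected with the boundary fit (no
#' extrapolation of the local polynomial).
#'
#' @param values positive per-amplicon values (NA/non-positive entries pass
#'   through untouched).
#' @param covariate numeric covariate (GC fraction or length).
#' @param span LOESS span (default 0.3).
#' @param degree local polynomial degree (default 2).
#' @param min_points minimum usable points required to fit (default 50).
#' @return Corrected values, same length as `values`.
#' @export
loess_detrend <- function(values, covariate, span = 0.3, degree = 2,
                          min_points = 50) {
  use <- is.finite(values) & values > 0 & is.finite(covariate)
  if (sum(use) < min_points)
    stop("too few usable amplicons (", sum(use), " < ", min_points,
         ") to fit a trend")
  if (diff(range(covariate[use])) == 0) {
    warning("constant covariate: no trend to remove")
    return(values)
  }
  lv <- log(values[use])
  cv <- covariate[use]
  fit <- loess(lv ~ cv, span = span, degree = degree,
               family = "symmetric")
  # clamp to the fitted support, then predict
  cvc <- pmin(pmax(cv, min(cv)), max(cv))
  f <- predict(fit, newdata = data.frame(cv = cvc))
  out <- values
  out[use] <- exp(lv - f + mean(f))
  out
}

#' Full library-specific normalization of one sample
#'
#' Applies, in order: library-size normalization, GC LOESS detrending,
#' length LOESS detrending. Amplicons with zero raw counts are masked for
#' this sample (their NRC stages are kept but flagged unusable).
#'
#' @param counts raw count column.
#' @param panel an [amplicon_panel()] supplying `gc` and `length`.
#' @param total_reads library size `N` (default `sum(counts)`).
#' @param span LOESS span for both fits.
#' @param sample name recorded in the result.
#' @return A `normalized_profile`: list with `sample`, `nrc_lib`, `nrc_gc`,
#'   `nrc_len`, `mask` (TRUE = usable), `panel`.
#' @export
normalize_sample <- function(counts, panel, total_reads = sum(counts),
                             span = 0.3, sample = "sample") {
  stopifnot(length(counts) == nrow(panel))
  mask <- counts > 0
  nrc_lib <- normalize_library_size(counts, total_reads)
  if (sum(mask) < 50) {
    # tiny panels cannot support a LOESS trend fit; skip the covariate
    # corrections rather than refuse the sample
    warning("fewer than 50 usable amplicons: skipping GC/length detrending")
    nrc_gc <- nrc_len <- ifelse(mask, nrc_lib, NA_real_)
  } else {
    nrc_gc <- loess_detrend(ifelse(mask, nrc_lib, NA_real_), panel$gc,
                            span = span)
    nrc_len <- loess_detrend(nrc_gc, panel$length, span = span)
  }
  structure(list(sample = sample, nrc_lib = nrc_lib, nrc_gc = nrc_gc,
                 nrc_len = nrc_len, mask = mask, panel = panel),
            class = "normalized_profile")
}

#' Infer control sample genders from chrX dosage
#'
#' For each control computes `M = mean(NRC_Len on chrX) / mean(NRC_Lib)`.
#' A 1- vs 2-component Gaussian mixture is fitted to the `M` values and
#' selected by BIC (mclust). Two components: the lower-mean cluster is male.
#' One component: all male iff the common `M < threshold` (default 0.9),
#' else all female. With fewer than 3 controls only the 1-component model
#' can be fitted and the threshold rule applies.
#'
#' @param profiles list of `normalized_profile`s for the controls.
#' @param panel an [amplicon_panel()]; chrX recognised as `chrX` or `X`.
#' @param threshold single-cluster male cutoff on `M` (default 0.9).
#' @return data.frame with `sample`, `m_value`, `gender` ("male"/"female"),
#'   `n_components_selected`.
#' @export
infer_gender <- function(profiles, panel, threshold = 0.9) {
  on_x <- panel$chrom %in% c("chrX", "X")
  nm <- vapply(profiles, function(p) p$sample, "")
  if (!any(on_x)) {
    warning("panel has no chrX amplicons: labeling all controls female")
    return(data.frame(sample = nm, m_value = NA_real_, gender = "female",
                      n_components_selected = 1L, stringsAsFactors = FALSE))
  }
  m <- vapply(profiles, function(p) {
    use <- p$mask
    mean(p$nrc_len[use & on_x], na.rm = TRUE) /
      mean(p$nrc_lib[use], na.rm = TRUE)
  }, numeric(1))
  gmax <- min(2L, length(m) - 1L)
  ncomp <- 1L
  gender <- NULL
  if (gmax >= 2L && diff(range(m)) > 0) {
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
    fit <- suppressWarnings(
      mclust::Mclust(m, G = 1:2, modelNames = "E", verbose = FALSE))
    # accept the 2-component model only when the clusters are separated on
    # the scale of the chrX dosage effect (M differs by ~0.5 between
    # genders); tiny-spread splits are BIC overfits on small cohorts
    if (!is.null(fit) && fit$G == 2 &&
        diff(range(fit$parameters$mean)) > 0.2) {
      ncomp <- 2L
      male_cl <- which.min(fit$parameters$mean)
      gender <- ifelse(fit$classification == male_cl, "male", "female")
    }
  }
  if (is.null(gender))
    gender <- rep(if (mean(m) < threshold) "male" else "female", length(m))
  data.frame(sample = nm, m_value = m, gender = gender,
             n_components_selected = ncomp, stringsAsFactors = FALSE)
}

#' Double chrX raw counts of male controls
#'
#' Makes male control chrX coverage comparable with female controls before
#' the baseline is built. Autosomes are never modified. A `count_matrix` can
#' be corrected only once (stage flag).
#'
#' @param cm a [count_matrix()].
#' @param genders data.frame from [infer_gender()] covering `cm$samples`.
#' @return The corrected `count_matrix` with `gender_corrected = TRUE`.
#' @export
apply_gender_correction <- function(cm, genders) {
  stopifnot(inherits(cm, "count_matrix"))
  if (isTRUE(cm$gender_corrected))
    stop("count matrix is already gender-corrected; refusing to apply twice")
  on_x <- cm$panel$chrom %in% c("chrX", "X")
  g <- genders$gender[match(cm$samples, genders$sample)]
  if (anyNA(g)) stop("gender unknown for: ",
                     paste(cm$samples[is.na(g)], collapse = ", "))
  males <- which(g == "male")
  if (any(on_x) && length(males))
    cm$counts[on_x, males] <- 2L * cm$counts[on_x, males]
  cm$gender_corrected <- TRUE
  cm
}
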