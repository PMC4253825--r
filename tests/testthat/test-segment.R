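# segmentation, zero level, calibration, readjustment, outliers

step_profile <- function(vals, chrom = "chr1") {
  n <- length(vals)
  panel <- toy_panel(n = n, chrom = chrom,
                     gene = paste0("G", rep(seq_len(ceiling(n / 4)),
                                            each = 4, length.out = n)))
  fake_ratio(vals, panel)
}

test_that("a noiseless step yields exactly one breakpoint at the step", {
  prof <- step_profile(c(rep(0, 30), rep(0.585, 30)) +
                         rnorm(60, 0, 1e-4))
  segs <- segment_profile(prof, rep(1, 60), nperm = 500)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$last_id[1], 30)
  expect_equal(segs$wmean, c(0, 0.585), tolerance = 1e-3)
})

test_that("pure noise is rarely split", {
  splits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    prof <- step_profile(rnorm(200, 0, 0.1))
    nrow(segment_profile(prof, rep(0.1, 200), nperm = 400))
  }, numeric(1))
  expect_gte(mean(splits == 1), 0.95)
})

test_that("weights protect against breakpoints at known-noisy amplicons", {
  set.seed(105)
  vals <- rnorm(60, 0, 0.05)
  vals[30:32] <- 3                              # a 3-amplicon artifact
  sigma <- rep(0.05, 60); sigma[30:32] <- 10    # but known to be noisy
  prof <- step_profile(vals)
  segs_w <- segment_profile(prof, sigma, nperm = 500)
  expect_equal(nrow(segs_w), 1)                 # downweighted: no split
  # same data with uniform weights: the artifact forces structure
  segs_u <- segment_profile(prof, rep(0.05, 60), nperm = 500)
  expect_gt(nrow(segs_u), 1)
})

test_that("segmentation is shift-equivariant", {
  set.seed(107)
  vals <- c(rnorm(40, 0, 0.05), rnorm(20, 0.6, 0.05))
  prof1 <- step_profile(vals)
  prof2 <- step_profile(vals + 0.37)
  set.seed(1); s1 <- segment_profile(prof1, rep(0.05, 60), nperm = 300)
  set.seed(1); s2 <- segment_profile(prof2, rep(0.05, 60), nperm = 300)
  expect_equal(s1$first_id, s2$first_id)
  expect_equal(s2$wmean, s1$wmean + 0.37, tolerance = 1e-10)
})

test_that("segments partition the unmasked amplicons per chromosome", {
  set.seed(109)
  n <- 80
  panel <- toy_panel(n = n, chrom = rep(c("chr1", "chr2"), each = 40))
  panel <- amplicon_panel(rep(c("chr1", "chr2"), each = 40),
                          panel$start, panel$end, panel$gene, panel$gc)
  vals <- rnorm(n, 0, 0.1); vals[5] <- NA
  prof <- fake_ratio(vals, panel)
  segs <- segment_profile(prof, rep(0.1, n), nperm = 200)
  amap <- attr(segs, "amplicon_segment")
  expect_setequal(amap$id, which(!is.na(vals)))
  expect_equal(anyDuplicated(amap$id), 0)
})

test_that("the zero level is the dominant density cluster", {
  segs <- data.frame(chrom = "chr1",
                     first_id = c(1, 151), last_id = c(150, 170),
                     n = c(150, 20), wmean = c(0.00, 0.58),
                     sem = c(0.01, 0.02), segment = 1:2)
  attr(segs, "amplicon_segment") <-
    data.frame(id = 1:170, segment = rep(1:2, c(150, 20)))
  z <- find_zero_level(segs, seed = 5)
  expect_equal(z$zero_level, 0, tolerance = 0.02)
  expect_true(z$neutral[1]); expect_false(z$neutral[2])
  # degenerate case: a single segment is neutral by definition
  z1 <- find_zero_level(segs[1, ])
  expect_equal(z1$zero_level, segs$wmean[1])
  expect_true(z1$neutral)
})

test_that("three planted levels are recovered with the middle as zero", {
  set.seed(113)
  wm <- c(rep(0, 8), -0.7, -0.7, 0.58, 0.58)
  segs <- data.frame(chrom = "chr1", first_id = seq(1, 111, 10),
                     last_id = seq(10, 120, 10), n = 10,
                     wmean = wm + rnorm(12, 0, 0.01),
                     sem = 0.02, segment = 1:12)
  attr(segs, "amplicon_segment") <-
    data.frame(id = 1:120, segment = rep(1:12, each = 10))
  z <- find_zero_level(segs, seed = 6)
  expect_equal(z$zero_level, 0, tolerance = 0.03)
  expect_equal(z$neutral, abs(wm) < 0.1)
  # oracle: the kernel-density mode of the resampled points sits at ~0
  set.seed(6)
  draws <- unlist(lapply(1:12, function(i) rnorm(50, segs$wmean[i],
                                                 segs$sem[i])))
  d <- density(draws)
  expect_equal(d$x[which.max(d$y)], 0, tolerance = 0.05)
})

test_that("zero level is reproducible under a fixed seed and stable across seeds", {
  segs <- data.frame(chrom = "chr1", first_id = seq(1, 91, 10),
                     last_id = seq(10, 100, 10), n = 10,
                     wmean = c(rep(0, 7), 0.6, 0.6, -0.7),
                     sem = 0.02, segment = 1:10)
  attr(segs, "amplicon_segment") <-
    data.frame(id = 1:100, segment = rep(1:10, each = 10))
  z1 <- find_zero_level(segs, seed = 11)
  z2 <- find_zero_level(segs, seed = 11)
  expect_identical(z1$zero_level, z2$zero_level)
  expect_identical(z1$neutral, z2$neutral)
  across <- vapply(1:20, function(s)
    all(find_zero_level(segs, seed = s)$neutral == z1$neutral), logical(1))
  expect_gte(mean(across), 0.99)
})

test_that("calibration centers on the zero level and rescales sigma", {
  set.seed(117)
  n <- 60
  vals <- rnorm(n, 0, 0.2)
  prof <- step_profile(vals)
  segs <- segment_profile(prof, rep(1, n), nperm = 200)
  z <- find_zero_level(segs, seed = 3)
  cal <- calibrate(prof, segs, z, rep(1, n))
  expect_equal(cal$sigma_sample, sd((vals - z$zero_level)), tolerance = 1e-10)
  expect_equal(cal$log_ratio, vals - z$zero_level)
  expect_equal(cal$segments$wmean, segs$wmean - z$zero_level)
  expect_equal(cal$sigma_i_sample, rep(cal$sigma_sample, n))
})

test_that("calibrated per-amplicon sd recovers a planted heteroscedastic scale", {
  set.seed(119)
  n <- 400
  sigma_i <- runif(n, 0.5, 1.5)
  s_samp <- 0.12
  vals <- rnorm(n, 0, s_samp * sigma_i)
  prof <- step_profile(vals)
  segs <- segment_profile(prof, sigma_i, nperm = 200)
  z <- find_zero_level(segs, seed = 4)
  cal <- calibrate(prof, segs, z, sigma_i)
  rel_err <- abs(cal$sigma_i_sample - s_samp * sigma_i) / (s_samp * sigma_i)
  expect_lt(median(rel_err), 0.15)
})

test_that("copy numbers invert the expected-ratio relation", {
  expect_equal(estimate_copies(1.5), 3L)
  expect_equal(estimate_copies(0.5), 1L)
  expect_equal(estimate_copies(1.0), 2L)
  expect_equal(estimate_copies(1.5, ploidy = 4), 6L)
  expect_error(estimate_copies(-0.2), "positive")
})

# build a calibrated profile directly for readjustment tests
fake_calibrated <- function(vals, panel, seg_of, statuses) {
  segs <- do.call(rbind, lapply(sort(unique(seg_of)), function(s) {
    idx <- which(seg_of == s)
    data.frame(chrom = panel$chrom[idx[1]], first_id = min(idx),
               last_id = max(idx), n = length(idx),
               wmean = mean(vals[idx]),
               sem = sd(vals[idx]) / sqrt(length(idx)),
               status = statuses[s], cluster = s, segment = s)
  }))
  attr(segs, "amplicon_segment") <- data.frame(id = seq_along(vals),
                                               segment = seg_of)
  class(segs) <- c("cna_segments", "data.frame")
  structure(list(sample = "t", log_ratio = vals, segments = segs,
                 zero_level = 0, sigma_sample = 0.05,
                 sigma_i_sample = rep(0.05, length(vals)),
                 mask = rep(TRUE, length(vals)), panel = panel),
            class = "calibrated_profile")
}

test_that("a mis-positioned intragenic breakpoint is moved to the gene boundary", {
  set.seed(121)
  # genes of 8 amplicons; gene 2 entirely at 0.58 but the breakpoint was
  # placed 3 amplicons early, splitting it 5/3 between two segments
  panel <- toy_panel(n = 24, gene = rep(c("A", "B", "C"), each = 8))
  vals <- c(rnorm(8, 0, 0.02), rnorm(8, 0.58, 0.02), rnorm(8, 0, 0.02))
  seg_of <- c(rep(1L, 13), rep(2L, 3), rep(3L, 8))  # break 5/3 inside B
  cal <- fake_calibrated(vals, panel, seg_of,
                         c("neutral", "gain", "neutral"))
  out <- readjust_gene_breakpoints(cal, alpha = 0.01)
  amap <- attr(out$segments, "amplicon_segment")
  b <- amap$segment[panel$gene == "B"]
  expect_equal(length(unique(b)), 1)  # whole gene in one segment
  st <- out$segments$status[out$segments$segment == unique(b)]
  expect_equal(st, "gain")
})

test_that("a true intragenic break with tight noise is kept", {
  set.seed(123)
  # a balanced break needs enough amplicons and separation for both
  # one-mean t-tests to reject: 12 amplicons split 6/6 across a
  # high-level amplification
  panel <- toy_panel(n = 20, gene = rep(c("A", "B"), c(8, 12)))
  vals <- c(rnorm(8, 0, 0.01), rnorm(6, 0, 0.01), rnorm(6, 1.2, 0.01))
  seg_of <- c(rep(1L, 14), rep(2L, 6))
  cal <- fake_calibrated(vals, panel, seg_of, c("neutral", "gain"))
  out <- readjust_gene_breakpoints(cal, alpha = 0.01)
  amap <- attr(out$segments, "amplicon_segment")
  expect_equal(length(unique(amap$segment[panel$gene == "B"])), 2)
})

test_that("genes inside one segment are untouched", {
  set.seed(125)
  panel <- toy_panel(n = 16, gene = rep(c("A", "B"), each = 8))
  vals <- rnorm(16, 0, 0.05)
  cal <- fake_calibrated(vals, panel, rep(1L, 16), "neutral")
  out <- readjust_gene_breakpoints(cal)
  expect_equal(nrow(out$segments), 1)
  expect_equal(out$segments$wmean, cal$segments$wmean)
})

test_that("outlier P-values follow the Gaussian tail and BH oracle", {
  panel <- toy_panel(n = 20)
  vals <- rep(0.3, 20)
  vals[5] <- 0.3 + 1.959964 * 0.05   # 1.96 sigma from its segment mean
  cal <- fake_calibrated(vals, panel, rep(1L, 20), "neutral")
  cal$segments$wmean <- 0.3
  out <- call_outlier_amplicons(cal)
  expect_equal(out$p[out$id == 5], 0.05, tolerance = 1e-6)
  expect_equal(out$p[out$id == 1], 1)            # exactly at the mean
  expect_equal(out$q, oracle_bh(out$p))
  # random Ps against the brute-force step-up
  set.seed(127)
  vals2 <- rnorm(20, 0.3, 0.05)
  cal2 <- fake_calibrated(vals2, panel, rep(1L, 20), "neutral")
  cal2$segments$wmean <- 0.3
  out2 <- call_outlier_amplicons(cal2)
  expect_equal(out2$q, oracle_bh(out2$p))
})
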