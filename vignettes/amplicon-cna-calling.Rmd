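---
title: "Calling copy number aberrations from targeted amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy number aberrations from targeted amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliCNA)
```

## The problem

Targeted amplicon panels sequence a few hundred to a few thousand PCR
amplicons at very high depth. Read counts per amplicon carry copy-number
signal, but that signal is buried under amplicon-specific PCR efficiency
(orders of magnitude between amplicons), smooth GC-content and
amplicon-length biases that differ between libraries, and
technology-specific structure shared across samples run on the same
platform. ampliCNA recovers gene-level copy number aberrations (CNAs) from
this data using only a small panel of diploid control samples processed
with the same target-selection kit — no matched normal, no SNP/BAF
information.

## Read counting

Each aligned read is assigned to exactly one amplicon — the one with the
largest overlap in bp (ties go to the amplicon with the smaller start, a
deterministic convention). Amplicons that overlap each other reciprocally
by more than 75% of both lengths are merged beforehand, because reads
cannot be attributed between them reliably. Duplicate reads are **kept**:
the libraries are single-ended and ultra-deep, so duplicate removal would
distort counts far more than it removes artifacts. Secondary,
supplementary and unmapped alignments are excluded so each sequenced read
counts at most once.

## Library-specific normalization

For a sample with $N$ total reads over $R$ amplicons, the raw read count
$RRC_i$ is first scaled by the average $Avg = N/R$:
$NRC^{Lib}_i = RRC_i / Avg$, so a copy-neutral amplicon with typical
efficiency sits near 1. Two LOESS fits (local polynomial regression,
degree 2) then remove the smooth GC and length trends, in that order. The
fits operate on $\log NRC$ — the biases are multiplicative, hence additive
in log space — and each correction preserves the geometric mean, so the
stages don't drift. Covariate values outside the fitted support take the
boundary fit value rather than an extrapolated polynomial, which is the
conservative choice for amplicons of extreme GC or length. Amplicons with
zero counts are masked per sample; amplicons whose cohort-mean $NRC^{Lib}$
falls below 0.01 are excluded panel-wide as systematically dead. Panels
with fewer than 50 usable amplicons skip the LOESS stages entirely (with a
warning): a trend fit on so few points would be noise.

The default LOESS span is 0.3: wide enough to be smooth over hundreds to
thousands of amplicons, narrow enough to follow a genuinely curved GC
response. It is configurable (`loess_span`).

## Gender and chrX

Control cohorts mix genders. For each control the statistic
$M_i = \mathrm{mean}(NRC^{Len}\ \mathrm{on\ chrX}) /
\mathrm{mean}(NRC^{Lib})$ is computed; the denominator is the sample-wide
mean (≈ 1), so $M_i$ is essentially the relative chrX dosage — about 0.5
for males. A 1- vs 2-component Gaussian mixture over the $M_i$ is selected
by BIC (mclust). Two components: the lower cluster is male. One component:
everyone is male iff the common $M < 0.9$. Two guards make this robust on
tiny cohorts: with $n = 2$ only the 1-component model is fittable at all,
and a 2-component model is accepted only when the cluster means are more
than 0.2 apart — the dosage effect is ~0.5 by construction, so
tighter-spread splits are BIC overfits. Male chrX counts are doubled (once;
the correction is flagged and refuses to re-apply), after which the
baseline treats all controls as two-copy everywhere.

## The control baseline

Even after library-specific normalization, samples from one platform share
residual structure. The baseline captures it by PCA on the
amplicons × controls matrix of $\log NRC^{Len}$ (column-centred,
covariance PCA — the controls are same-technology replicates, so no
per-control variance scaling). Amplicons are the observations; the first
principal component is then essentially the shared per-amplicon efficiency
profile, and its scores correlate with the per-amplicon mean at
$r \ge 0.99$ on simulated cohorts. PC2/PC3 capture smaller shared biases,
so by default $k = \min(3, n-1)$ components are kept ($n$ = number of
controls; at least two are required). PC1's sign is fixed against the mean
profile for reproducibility.

Each sample (control or tumor) is regressed by OLS of its
$\log NRC^{Len}$ on the $k$ score columns plus an intercept. The residuals
are the sample's log copy-ratio profile; a global multiplicative shift
(library size mis-estimation) moves only the intercept.

## Per-amplicon noise: $\sigma_i = f(\mathrm{PC1})$

Amplicons differ in how noisy they are — mostly with coverage: high-PC1
(high-efficiency) amplicons are quieter. Each control's residual profile
is rescaled to overall variance 1 (samples differ in global noise), the
pooled squared residuals are regressed on PC1 by LOESS (degree 2), and
$\sigma_i = \sqrt{\max(\hat f(\mathrm{PC1}_i), 10^{-3})}$. Squared
residuals (not absolute) are used because the square-root back-transform
is then unbiased for normal noise. The variance floor prevents pathological
weights downstream. The pooled fit is thinned to at most 10,000
PC1-stratified points — the trend is broad, and the subsample keeps the fit
fast and well conditioned on large cohorts.

## Segmentation

Tumor log-ratio profiles are segmented per chromosome with a weighted
circular binary segmentation: every arc $(i{+}1..j)$ is compared with its
complement by
$Z = (\bar x_{arc} - \bar x_{comp}) / \sqrt{1/W_{arc} + 1/W_{comp}}$,
weighted means and weight sums using $w_i = 1/\sigma_i^2$ — so amplicons
known to be noisy cannot seed breakpoints. The maximal $|Z|$ is accepted as
a split if it beats the permutation distribution of the same statistic
(joint permutations of the (value, weight) pairs; default 1,000
permutations, $\alpha = 0.01$, with early termination once acceptance is
impossible). Splitting recurses until no segment can be split; every
resulting flank must hold at least 2 amplicons (`min_seg`), so single
outliers cannot form segments. The inner loop is implemented in C++; the
permutation stream uses R's RNG, so runs are reproducible under
`set.seed()`.

A consequence of the exchangeable permutation null worth knowing: isolated
1–2 amplicon artifacts are *never* significant (the permuted maximum
reaches the observed one whenever the artifact points land together, which
is too likely), and chromosomes where a large fraction of amplicons is
aberrant (≳30%) have a contaminated null that can push composite-segment
p-values to the edge of $\alpha$. With CNAs on ~20% of genes spread across
chromosomes — the regime the method is intended for — recovery is
reliable.

## The zero level

Segment means cluster at integer copy levels, but which level is
copy-neutral is not known a priori (the profile is only relative). Each
segment's weighted mean is resampled 50 times with Gaussian noise of sd
equal to its standard error — a sampling version of Parzen smoothing in
which long, confident segments contribute sharp mass — and a 1-D
equal-variance Gaussian mixture (1–9 components, BIC) is fitted to the
draws. The neutral level is the component at the maximum of the fitted
mixture density, ties resolved toward 0.

Two numerical details matter. The mixture routinely places several
*duplicate* components on one strong level; ranking components by their own
weight would then understate that level. Components whose means are closer
than half the common component sd are therefore collapsed into levels
first, and levels are ranked by the full mixture density at the level
mean. Second, the resampling is seeded (`seed`), making the call
bit-for-bit reproducible; across seeds the neutral assignment is stable
whenever the levels are separated.

All log ratios and segment means are centred on the zero level. Segments
clustered with zero are copy-neutral; the others are gain or loss by sign.
The per-sample scale is
$\sigma_{sample} = \mathrm{sd}(\log ratio_i / \sigma_i)$ over neutral
amplicons, and $\sigma_i^{sample} = \sigma_{sample}\,\sigma_i$ calibrates
every subsequent test.

## Statistical validation

For a candidate segment of $n$ amplicons, let
$X_i = \log(NRC^{final}_i)/\sigma_i^{sample}$.

* **Fixed variance test**: under neutrality $X_i \sim N(0,1)$, so
  $|\bar X|$ is half-normal and
  $P = 2(1 - \Phi(|\bar X|\sqrt n))$.
* **t-test**: one-sample, two-sided, $n-1$ df — more conservative because
  the sd is estimated. Undefined for $n < 2$ or zero sd; such segments
  fail the filter by convention.
* **Purity band**: a CNA of $l$ copies carried by a fraction $c$ of cells
  in a tumor of ploidy $P$ has expected ratio
  $\mathrm{ExpectedNRC} = (1-c) + c\,(1 \pm l/P)$. Candidates whose
  weighted geometric mean of linear ratios (weights $1/\sigma_i^2$; the
  geometric mean of ratios is exactly $e^{\bar x_w}$ of the centred logs)
  lies inside $(0.875, 1.125)$ are indistinguishable from noise-level
  dilution and are filtered. Solving the boundary at $l = 1$ gives the
  detection limits $c_{min} = 0.125\,P$: 25% of cells for diploid, 50%
  for tetraploid tumors.

A candidate survives only if both tests give $P < 0.01$ **and** it falls
outside the band. Failing candidates are demoted to neutral with a reason
flag rather than dropped, so gene tables always cover the panel. The band
is applied after zero-level centring (it is symmetric around 1).

Copy numbers are reported as $\mathrm{round}(P \cdot ratio)$ under the
stated ploidy (default 2) alongside the continuous ratio.

## Gene-aware readjustment and outliers

Breakpoints occasionally land a few amplicons inside a gene although the
true break sits at the gene boundary. For every gene split by a
breakpoint, each adjoining segment mean is tested (one-sample t-test)
against all of the gene's log ratios; if the best P exceeds 0.01 the whole
gene is reassigned to that segment, otherwise the intragenic break is
treated as real. Genes with more amplicons reassign more reliably; note
that a perfectly balanced split of a small gene (e.g. 4+4 amplicons one
copy apart) inflates the within-gene sd enough that neither test rejects —
such genes are absorbed into one side. This is an inherent small-$n$
property of the test, not a coding choice.

Separately, every amplicon gets a two-sided P-value under
$N(wm_{seg}, \sigma_i^{sample})$ with Benjamini–Hochberg correction across
the sample, flagging single-amplicon outliers at $q < 0.05$. These are
reported but never promoted to CNA calls.

## The simulator

`simulate_cohort()` generates control cohorts and tumors with planted
CNAs: per-amplicon Poisson counts with rate
$depth \cdot e_i \cdot b_{GC}(gc_i) \cdot b_{len}(len_i) \cdot
cr_i \cdot \eta$, where $e_i$ is a fixed lognormal amplicon efficiency
(log-sd 0.5), $b_{GC} = e^{-k(gc-0.5)^2}$ ($k=4$) emulates the unimodal GC
response, $b_{len} = e^{-k(len-70)/70}$ ($k=1$) the preference for short
fragments, $\eta$ a per-amplicon, per-sample lognormal technology noise
(log-sd 0.1), and $cr_i$ the true copy ratio from the purity model above
(males halve chrX). Defaults — 40 genes × 8 amplicons, 70–140 bp, GC
0.3–0.7, depth 1,000, 15 controls — are the study conditions used by the
test-suite. Poisson counts (rather than negative binomial) are the default
because at this depth the explicit efficiency and technology-noise terms
dominate the variance; `overdispersion_sd` adds lognormal overdispersion
if wanted.

What the simulator does **not** emulate: mappability structure, positional
correlation of biases along the genome, FFPE degradation profiles,
subclonal mixtures of different CNAs in one gene, and real breakpoints
inside amplicons. Passing tests therefore demonstrate correctness of the
method's machinery under its stated noise model, not performance on any
particular clinical panel.

## Worked example

```{r example, eval = FALSE}
spec <- data.frame(gene = c("GENE003", "GENE011"),
                   direction = c("gain", "loss"), l = 1, c = 1)
sim <- simulate_cohort(sim_config(n_genes = 20, cna_spec = spec),
                       n_tumors = 1, seed = 5)

ctrl <- sim$counts
ctrl$counts <- ctrl$counts[, sim$control_names]
ctrl$samples <- sim$control_names
ctrl$total_reads <- ctrl$total_reads[sim$control_names]

baseline <- run_control_phase(ctrl)
res <- run_tumor_phase(sim$counts$counts[, "tumor01"], baseline, seed = 3)
subset(res$genes, status != "neutral")
plot(res)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `loess_span` | 0.3 | span of the GC/length LOESS fits |
| `min_mean_nrc` | 0.01 | panel-wide dead-amplicon threshold on cohort-mean NRC |
| `gender_threshold` | 0.9 | single-cluster male cutoff on $M$ |
| `n_pcs` | min(3, n−1) | baseline components |
| `alpha` | 0.01 | CBS permutation acceptance level |
| `nperm` | 1000 | CBS permutations per split test |
| `min_seg` | 2 | minimum amplicons per segment |
| `m_draws` | 50 | resampling draws per segment for the zero level |
| `p_threshold` | 0.01 | CNA significance threshold (both tests) |
| `ratio_band` | (0.875, 1.125) | undetectable-ratio band |
| `ploidy` | 2 | assumed ploidy for copy-number estimates |

## Known limitations

* All calls are **relative** to the detected zero level. If (almost) every
  gene on a small panel gains a copy, the zero level follows the majority
  and everything reads neutral — demonstrated in the test-suite on a
  two-gene panel with a global gain.
* One-amplicon events are reported as outliers only, never as CNAs.
* Purity $c$ and ploidy $P$ are not estimated from the data; CNAs diluted
  below the band boundary (e.g. < 25% of cells at $l=1$, $P=2$) are
  deliberately filtered.
* No B-allele-frequency modeling; copy-neutral LOH is invisible.
* Chromosomes where a large fraction of amplicons is aberrant weaken the
  permutation null of the segmentation (see above).

## Problem sizes used by the tests

The suite exercises panels of 16–2,000 amplicons, cohorts of 2–15
controls, and 20,000-segment null simulations; the end-to-end recovery
runs use 40 genes × 8 amplicons with one-copy gains/losses on 8 genes at
$c = 1$, noise log-sd 0.1 — sizes chosen to make every behavior visible
while keeping a full run in well under a minute per case.
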