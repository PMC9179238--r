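---
title: "High-resolution differential cell counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-resolution differential cell counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

High-resolution differential cell counts (HRDCCs) resolve the somatic cells
of bovine milk — and the leukocytes of matched blood samples — into their
immunological subpopulations by flow cytometry: granulocytes (with
eosinophils and CD11b-low immature granulocytes), monocytes/macrophages
(classical, intermediate and nonclassical monocytes in blood; classical and
nonclassical macrophages in milk), and lymphocytes (NK, gamma-delta T,
CD4+ T, CD8+ T and B cells), plus overall cell viability and, in milk,
mammary epithelial cells (MECs, pan-cytokeratin-positive among CD45-negative
cells). Followed over a whole lactation, these percentages form a
longitudinal immunomonitoring record in which early lactation, inflammation
episodes and cow-level individuality all leave signatures.

The package provides four connected layers:

1. a **synthetic study generator** that emulates an eight-cow herd sampled in
   milk and blood twice weekly to 100 days in milk (DIM) and weekly to the
   end of lactation (291–305 d), down to event-level cytometry samples with
   known truth labels;
2. a **hierarchical gating engine** with a fixed-threshold *reference* mode
   and a data-driven *auto* mode (kernel-density valley detection);
3. **longitudinal description**: robust outlier flagging, cubic polynomial
   and four-knot spline trends, per-cow summaries, and haptoglobin-defined
   inflammation **episode** analysis;
4. **multivariate phase analysis**: PCA and sparse PLS-DA over six 50-DIM
   lactation phases with one-vs-rest AUROCs and feature ranking.

Because no event-level reference data are distributable, every layer is
validated against the generator's retained ground truth plus independent
numerical oracles.

## The synthetic study

`study_config()` fixes the study conditions; `simulate_study()` draws a
herd. The latent state of each visit is the vector of terminal population
fractions (summing to exactly 1) plus viability; event matrices are
regenerated on demand from per-sample seeds (`events_for_sample()`), so a
full 44-million-event study needs no storage and is bit-reproducible.

Key defaults, with the reasoning behind them:

* **Schedule.** Visits on days 2 and 5 of each week up to 100 DIM, then
  weekly; a per-visit dropout probability of 0.035 brings the mean from ~57
  scheduled to ~55 realised visits per cow, the realistic case of missed
  samplings.
* **Milk dynamics.** Gamma-delta T cells decline linearly from ~40% to ~8%
  of lymphocytes over the lactation while CD4+ T cells rise in mirror image;
  NK cells decline and nonclassical macrophages slowly expand; granulocyte
  and lymphocyte fractions carry a per-visit SD of 0.10 before 150 DIM and
  0.04 after (the early-lactation "fluctuation, then level-out" pattern);
  macrophages stay low (~10% of CD45+). Viability starts low (~40%),
  recovers with a 25-day time constant and keeps creeping upward
  (8e-4/day, capped at 99.5%).
* **Blood dynamics.** Stationary around cow-specific baselines. Two named
  profiles pin the blood CD4+ baseline to 34.7% (per-visit SD 2.9) and
  19.7% (SD 2.6) of lymphocytes; the remaining cows draw their baseline
  from a between-animal distribution (mean 27%, SD 4.5%). Milk CD8+ T
  percentages exceed blood ones and B cells show the opposite contrast, a
  structural property of the species.
* **Episodes.** Poisson(0.6) inflammation episodes per lactation, 14–22 d
  long; within an episode haptoglobin rises by 1.5 units over a baseline of
  1.0 (SD 0.15, arbitrary units — the episode threshold convention is
  baseline + 3 SD) and milk gamma-delta T shifts down / CD4+ T up by 8
  points of the lymphocyte pool. The immature-granulocyte fraction is
  deliberately never episode-linked, preserving a known null. A quarter of
  cows additionally show a decaying calving-window haptoglobin elevation.
* **Biomarkers.** NEFA, beta-HBA and bilirubin are elevated post partum
  and decay exponentially (negative energy balance); calcium dips briefly;
  GLDH decays slowly; all strictly positive with log-normal noise.
* **Events.** 50,000 events per sample (typical acquisition; configurable).
  Marker intensities are drawn per population on the arcsinh-transformed
  scale and emitted as compensated raw intensities (`cofactor * sinh(z)`,
  cofactor 150); scatter is linear. Nuisance classes exist to be excluded:
  5% debris (low FSC/SSC), 3% doublets (FSC-A ≈ 2 × FSC-H) and dead cells
  (high viability-dye signal) at the rate implied by the sample's
  viability. Milk samples before 50 DIM omit the panCK channel entirely,
  so downstream code must treat the MEC gate as genuinely missing, not
  zero.

What the generator does **not** emulate: spillover/compensation (data are
simulated on compensated scale), instrument drift, absolute cell
concentrations (only fractions), non-Gaussian marker shapes, and gating
ambiguity from continuum phenotypes. Passing tests therefore demonstrate
the correctness and calibration of the pipeline, not the biological
variability of real herds.

## The gating hierarchy

After arcsinh transformation, nuisance exclusion removes debris (joint
FSC-A/SSC-A gate), doublets (FSC-A/FSC-H > 1.5) and dead events; viability
is live singlets as a share of non-debris singlets. CD45+ events are split
by SSC into lymphocytes / monocytes-macrophages / granulocytes; the
granulocyte branch separates eosinophils by autofluorescence and immature
granulocytes by low CD11b; the monocyte branch is a CD14 × CD16 quadrant
(milk ncMac pools both CD16+ quadrants, the CD14+/- CD16+ definition); the
lymphocyte branch gates NK, gamma-delta T, CD4+, CD8+ and B cells
sequentially, so every event lands in at most one terminal population.

Percentages are reported percent-of-parent, with percent-of-CD45+ emitted
alongside; percent-of-parent is the convention under which a blood CD4+
value of ~35% is interpretable (as a share of lymphocytes). Switching the
denominator rescales but never reorders siblings.

**Reference mode** uses fixed thresholds at the midpoints of the
positive/negative signature locations — the stand-in for manually placed,
FMO-informed gates. **Auto mode** re-derives each threshold per sample as
the kernel-density valley between the two highest well-separated modes
(Silverman bandwidth, doubled for stability; three modes for the SSC
split). Three guards make the valley search robust: a candidate mode must
reach at least 1.5% of the dominant peak height (rejecting stray-event
spikes in the tails), the density between two modes must dip below 60% of
the smaller peak (rejecting shoulder artefacts), and every group implied
by the cuts must hold at least 1% of the events (rejecting tail sampling
artifacts of a single Gaussian). When a channel is genuinely unimodal — all
events positive on CD45, say — the engine anchors on the template
(reference) threshold, the same pattern-anchored behaviour as
template-driven automated gating tools; the exported `auto_threshold()`
also offers a plain quantile fallback. Parents with fewer than 500 events
keep template thresholds.

Concordance between the modes is quantified by pooling all
(sample × node) percentage pairs and fitting a simple linear regression
(`compare_gating()`), reporting n, Pearson r, slope, intercept and p.

## Longitudinal description

`rout_outliers()` follows the robust-fit-then-FDR-flag recipe: an
iteratively reweighted (Tukey bisquare) cubic, residuals standardised by
the robust scale estimate, two-sided t-tail probabilities, and a
Benjamini–Hochberg rule at rate Q (default 1%). This is an open
re-implementation of the commercial ROUT procedure; numerical identity
with the commercial implementation is not claimed. Outlier elimination
always precedes trend fitting. `fit_poly3()` is least squares on the
unflagged points; `fit_spline4()` is a cubic regression spline with four
interior knots at the 20/40/60/80% DIM quantiles — a fixed-knot analogue
of "smoothing spline with four knots" that keeps the fit linear and
testable. Series shorter than 10 points are left unflagged with a warning;
rank-deficient designs error.

Trend pooling: series are per cow; figure-style summaries pool per-sample
values across cows rather than averaging per-DIM means first (the two are
equivalent on balanced schedules, and pooling is the simpler convention).

## Episodes

`detect_episodes()` calls an episode for every maximal run of at least
`min_consecutive` (default 2) consecutive visits with haptoglobin above
threshold; a single sub-threshold visit splits runs. The threshold default
is baseline + 3 baseline-SD since the assay units are arbitrary. The
calving-window elevation is flagged like any other episode — no special
case. `episode_contrast()` reports the in-minus-out mean difference with a
two-sided Wilcoxon rank-sum test and declines (with a reason) when either
side has fewer than 3 visits. `marker_correlation()` (Pearson with a
Fisher-z interval) serves the immature-granulocyte null check.

## Phase analysis

`bin_phases()` maps DIM to six 50-day phases (the last spanning 251–305).
`assemble_matrix()` joins milk and blood results of the same visit with the
biomarkers, drops MEC and incomplete rows (no imputation — none is
reported for this design), and standardises every feature. PCA is the SVD
of that matrix; its explained variances equal the correlation-matrix
eigenvalue spectrum, which the tests assert at 1e-8.

`fit_splsda()` re-implements sparse PLS-DA: dummy-coded class matrix,
NIPALS iterations with soft-thresholding of the X-loading to the `keepX`
largest-magnitude entries (default 5 per component, 2 components; `keepX`
is not reported for the original analysis, so it is a configurable
default), convergence at 1e-6 or 500 iterations, regression deflation
(hence orthogonal scores). With `keepX = p` it reduces to dense PLS-DA,
which the tests verify against an independent implementation at score
correlation ≥ 0.999. Class scores are dummy-response regression
predictions; one-vs-rest AUROC is the Mann–Whitney statistic of the
phase's score column, computed on the training data — the single-fit
convention matching reported caption AUROCs; cross-validation is
deliberately not the default. `top_features()` ranks by absolute
component-1 loading with component-2 tie-breaks.

## Numerical choices and degenerate inputs

* Seeds fan out per animal/sample through a counter-based hash, so any
  sample can be regenerated in isolation; identical seed + config gives
  bit-identical studies.
* Fractions are clamped away from 0/1 and renormalised row-wise; terminal
  fractions sum to 1 within 1e-9.
* FCS files are written as FCS 3.1 list-mode with doubles, so the
  round trip is exact; truth labels travel in a `*_truth.csv` sidecar
  keyed by event index, never inside the FCS. Truncated files error with
  the offending byte offset.
* Constant inputs error in `auto_threshold()`, `fit_pca()` (constant
  columns) and `marker_correlation()`; all-removed samples are flagged by
  `exclude_nuisance()` with the sample named.

## Problem sizes used by the tests

The default study (8 cows × ~55 visits × 2 matrices at 50,000
events/sample) is simulated and gated once, in both modes, for the
acceptance checks; unit tests run on a 2-cow, 10-visit, 8,000-event
fixture. Monte-Carlo checks use 20–200 replicates. These sizes were chosen
so the whole suite exercises the full default study while remaining
routine to run on a single CPU.

## Known limitations

* Reference-mode thresholds derive from the simulation's own signature
  midpoints; with real FCS files they must be supplied from FMO-informed
  manual gates.
* The auto mode is a faithful re-creation of template-driven density
  gating, not a byte-for-byte port of any specific tool's undisclosed
  parameters.
* Explained-variance percentages of PCA/sPLS-DA on synthetic data are
  properties of the generator, not of any real herd, and are not
  acceptance surfaces.
* Absolute somatic cell counts (cells/mL) are out of scope; the pipeline
  works in percentages throughout.
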