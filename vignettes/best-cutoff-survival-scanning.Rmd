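---
title: "Best-cutoff survival scanning for prognostic biomarker ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-cutoff survival scanning for prognostic biomarker ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large compendia of breast-cancer microarray cohorts with relapse-free
survival (RFS) follow-up make it possible to rank *every* measured gene by
its prognostic strength within a clinically defined subgroup — for example,
chemotherapy-treated ER-positive/ERBB2-negative patients, or basal
(ER-negative/ERBB2-negative) patients. `survscan` implements that pipeline:
array-level quality control and scaling normalization, removal of
re-published arrays, receptor-status calling from probe intensities, cohort
selection by subtype and documented systemic treatment, a best-cutoff Cox
scan per gene with false-discovery-rate control, a filter cascade that
keeps only robustly expressed genes, and ranking by absolute hazard ratio.

Because the original compendium is assembled from dozens of public series,
the package ships a synthetic cohort generator that emulates the
*structure* of such data — multi-dataset batch scales, MAS5-like skewed
non-negative intensities, proportional-hazards survival with planted
prognostic genes, right censoring, duplicated arrays, QC failures — so that
every stage is testable against a known ground truth without any external
download.

## The statistical core

For a gene with expression $x_1, \dots, x_n$ and survival data
$(t_i, \delta_i)$, every distinct observed value $c$ between the lower and
upper quartiles ($Q_1 \le c < Q_3$) defines a dichotomization
$z_i = \mathbf{1}(x_i > c)$. For each candidate the package fits the Cox
proportional-hazards model

$$ h_i(t) = h_0(t)\, e^{\beta z_i} $$

by Newton–Raphson maximization of the partial likelihood with the Efron
correction for tied event times (Breslow available), and computes a
p-value from the score test at $\beta = 0$, which for a binary covariate
is the log-rank test (a Wald p-value is available). The scan reports the
cutoff with the smallest p-value; exact p ties are broken by the largest
absolute hazard ratio $\max(\mathrm{HR}, 1/\mathrm{HR})$, remaining ties
by the smallest cutoff. Benjamini–Hochberg q-values are then computed
across the best p-values of all gene-mapped probes.

Selecting the minimum p-value over many correlated cutoffs is an optimistic
statistic: under the global null the per-gene best p is stochastically
smaller than uniform, and BH control over such minima is anti-conservative.
This is a known property of the published procedure and is reproduced
as-is, not "corrected"; the package therefore also exposes a fixed-cutoff
mode (`scan_transcriptome(..., scan = FALSE)`, median split) whose null
calibration is verified in the test suite — distinguishing base-test
calibration from minimum-p selection inflation.

Restricting cutoffs to $[Q_1, Q_3)$ guarantees each arm keeps at least a
quarter of the cohort (minus one), so no fit rests on a handful of extreme
samples. Genes that are constant within the interquartile range are
unscannable; genes with all events in one arm at every cutoff (monotone
partial likelihood) are non-estimable. Both are excluded from the FDR
vector and reported separately.

## Preprocessing and cohort definitions

* **Scaling normalization** multiplies every array so its mean over a fixed
  reference probe set equals 1000 — the second-pass batch correction used
  after per-array summarization. All downstream intensity thresholds assume
  this scale.
* **QC classification** uses five per-array parameters: background, raw Q,
  percentage of present calls, presence of BioB/C/D spikes, and the
  GAPDH/ACTB 3'/5' ratio. A continuous parameter fails when it is
  non-positive or falls outside the central 95% range across all arrays
  (2.5th–97.5th percentile, inclusive, linear-interpolation percentiles —
  the estimator is a package choice, configurable in principle; a one-sided
  0–95% reading of "95% range" would flag only high values, which does not
  match parameters where *low* values indicate failure, such as percent
  present). One failing parameter makes an array an *outlier* (flagged,
  retained); two or more make it *biased* (excluded).
* **Redundancy removal** collapses arrays with identical expression vectors
  (after rounding to six significant digits) to the copy from the earliest
  published dataset, ties broken by sample id. Comparison happens on the
  normalized scale; per-array scaling maps exact copies to exact copies,
  so the choice of scale does not affect which arrays are recognized as
  duplicates.
* **Receptor calls**: ER positive means probe `205225_at` strictly above
  500; ERBB2 positive means probe `216836_s_at` strictly above 4800.
  Values exactly at a cutoff are negative — the boundary convention is the
  package's choice and is exposed as an argument. Progesterone receptor is
  not assessed (no reliable probe on the platform family).
* **Treatment filters** act on documented systemic therapy only
  (chemotherapy, endocrine therapy); samples with unknown treatment are
  excluded, and the untreated cohort requires documented absence of
  systemic therapy. Radiation therapy is ignored.

## The filter cascade

After the scan, results pass five sequential filters: gene-mapped probes
only; FDR q ≤ 0.05; maximal expression strictly over 1000 (the
post-normalization global mean, so the gene must be robustly measurable in
at least one sample); best cutoff strictly over 100 (clear of background
noise); and the designated best probe per gene only. The best-probe stage
filters by probe *identity*, not by effect size: if a non-best probe of a
gene outranks the best probe, it is still removed. Survivors are ranked by
absolute hazard ratio, descending.

## What the synthetic generator emulates

`sim_config()` defaults encode the study conditions used throughout the
tests: 5 datasets × 80 samples, 1,000 generic probes plus the two receptor
probes, 20 planted prognostic probes with |log HR| = log 2.5, a 60-month
baseline median survival with ~30% right censoring, per-dataset batch
scales in [0.6, 1.8], 70% ER-positive and 15% ERBB2-positive samples, half
the cohort with documented systemic treatment and 30% documented untreated.

Design choices worth knowing:

* **Planted effects act through a latent risk factor.** The planted probes
  are co-expressed (bimodal, two log-normal components two log-standard
  deviations apart) readouts of one latent binary risk class, with random
  orientation per probe, and the hazard multiplier is
  $\exp(\beta\, z_{\text{latent}})$. This mirrors real prognostic
  signatures (co-expressed proliferation modules) and makes parameter
  recovery well defined: each planted probe's own dichotomization at its
  median carries a marginal log HR of ±β. Had each of 20 probes carried an
  *independent* additive effect of this size, omitted-covariate
  attenuation in the marginal Cox fits would shrink every per-gene
  estimate well below the generating value and "recovery" would not be a
  property of the estimator.
* **Planted probes are drawn from the well-expressed intensity range and
  are flagged as best probes of their genes**, since the cascade is
  explicitly designed to retain only robustly expressed best probes; the
  recovery experiments measure the statistics, not an intentional
  exclusion by expression level.
* **Survival** is exponential by default (Weibull shape configurable),
  median fixed by `baseline_median_survival`; censoring is uniform on
  $(0, c)$ with $c$ calibrated by bisection against the realized event
  times — standard, reproducible, with a closed-form check.
* **QC parameters of clean arrays are comonotone by cyclically shifted
  ranks** (shift $n/4$ per parameter), so no clean array can fall in the
  outer 2.5% tail of two parameters simultaneously. Planted failures sit
  12 standard deviations out, and planted arrays take central values on
  their non-failing parameters. Consequence: *biased* labels identify
  exactly the planted biased arrays, while roughly 20% of clean arrays are
  single-parameter outliers (by construction of the 95% range, some
  fraction of clean arrays always sits in exactly one tail). Real QC
  parameters are positively correlated rather than comonotone; the
  construction trades that realism for an exact, testable ground truth.
* **Duplicates** are exact column copies of earlier-dataset arrays,
  re-assigned to the last dataset, sharing the original's clinical record.
* **One RNG stream per stage**, each derived from the master seed, so
  adding or reconfiguring one stage never perturbs another stage's draws.

What the generator does *not* emulate: probe-level (CEL) data, platform
differences in probe membership, correlated QC failures, non-proportional
hazards, dataset-specific follow-up distributions, and gene–gene
correlation beyond the planted module. Passing recovery tests therefore
demonstrates correctness of the estimators and filters under a clean
proportional-hazards world, not performance on real compendia.

## Numerical choices

* Newton–Raphson on β with step-halving, tolerance 1e-8, at most 50
  iterations; divergence (|β| > 15), monotone likelihood, or
  non-convergence → non-estimable.
* Quartiles and percentiles use linear interpolation between order
  statistics (type 7, the R default).
* Exact floating-point equality defines a p-value tie in the cutoff scan;
  the tie chain (smallest p → largest absolute HR → smallest cutoff) makes
  the selected cutoff unique and permutation-stable.
* Whether the quartile endpoints themselves are eligible cutoffs is
  settled as $[Q_1, Q_3)$: candidate cutoffs are the distinct observed
  values at or above $Q_1$ and strictly below $Q_3$.
* Overlap percentages round half-up to one decimal for report parity.

## Problem sizes used in the shipped analyses and tests

The `analysis/` scripts and the acceptance checks run at the generator's
default scale (400 samples × ~1,000 probes; 25 replicates for the recovery
experiment, 3 pooled null cohorts of 1,000 probes for calibration, 100
small datasets for the likelihood-oracle comparison). These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping a
full run in minutes on a single core; they are the package's chosen study
conditions, and all seeds are fixed in the scripts.

## Known limitations

* The minimum-p scan's q-values are anti-conservative by construction
  (reproduced as published); treat the FDR filter as a ranking device, not
  a calibrated error rate.
* Single-covariate fits only: no covariate adjustment, stratification, or
  proportional-hazards diagnostics.
* The score/Wald p-values are asymptotic; in very small cohorts (tens of
  samples) with few events, calibration degrades before the scan's
  quartile restriction does.
* Receptor calls inherit the intensity scale: they are only meaningful on
  arrays normalized to the mean-1000 anchor.
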