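---
title: "Co-fluctuation-resolved connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-fluctuation-resolved connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofluct)
```

## The analysis in one paragraph

Functional connectivity (FC) between two brain parcels is the Pearson
correlation of their BOLD time series. Writing both series as population
z-scores, that correlation is exactly the time-average of the per-frame
product `z_i(t) * z_j(t)` — the *edge time series* (ETS). The root sum of
squares (RSS) of all edges at a frame measures how strongly the whole brain
co-fluctuates at that moment. Ranking frames by RSS and recomputing FC from
chosen subsets — the top or bottom percentage (sequential sampling), one of
`n_bins` equal rank bins (individual bins), or the union of two bins
(combined bins) — yields *co-fluctuation-resolved* FC estimates. The package
then asks two questions of each estimate: how well does it fingerprint
subjects across scan days (identification accuracy and differential
identifiability), and how well does it predict phenotypes under nested,
family-grouped, confound-consistent cross-validation (Pearson-kernel ridge
regression, CBPM, a ridge classifier)? A Bayesian
region-of-practical-equivalence (ROPE) test decides whether a sampling
strategy's cross-validated scores are practically equivalent to full-FC
scores, and structure–function coupling correlates each FC estimate with the
subject's streamline-count matrix.

## The ETS identity and z-scoring convention

`compute_ets()` z-scores each parcel with the *population* standard
deviation (denominator `n`, not `n - 1`). With this convention

```
mean_t [ z_i(t) z_j(t) ] = r_ij   (full-run Pearson correlation, exactly)
```

so the ETS is an exact temporal decomposition of FC; the test-suite asserts
the identity to 1e-12 on random runs. With the sample-sd convention the
identity would only hold up to a factor `(n-1)/n`. Frame ranking by RSS is
stable: ties (measure-zero for real data) break by ascending frame index.

FC from a frame subset recomputes means and standard deviations *on the
subset* — plain Pearson correlation of the extracted sub-series. The
alternative of reusing full-run z-scores would make subset FC a rescaled
partial sum of the ETS; it is not what "Pearson correlation on the selected
time points" means, so it is not the default (no hidden flag switches the
test behaviour).

## Fingerprinting metrics

For FC vectors from day 1 and day 2 (each the average across the two
phase-encoding runs of that day), the similarity matrix holds Pearson
correlations between every day-1/day-2 subject pair. Identification
accuracy is the fraction of subjects whose maximal similarity lies on the
diagonal, computed over rows (day 1 as source) and columns (day 2 as
source) and averaged. A tied maximum counts as a *failure*: the conservative
convention keeps the metric deterministic, and the degenerate case (all
subjects identical, accuracy 0) is asserted in the tests. Differential
identifiability is `(I_self - I_other) * 100` with `I_self` the mean
diagonal and `I_other` the mean of all off-diagonal entries of the single
cross-day matrix. Whether `I_self`/`I_other` should also average both
directions is not settled usage; we use the one cross-day matrix (the
common definition in the identifiability literature) while accuracy
explicitly uses both directions.

The bootstrap resamples subjects with replacement (default 1000 draws),
keeps the unique subjects of each draw, and recomputes both metrics on that
subset of the precomputed similarity matrix — algebraically identical to
recomputing from the FC vectors, and much cheaper. Draws with fewer than
two unique subjects are redrawn; at realistic cohort sizes this has
vanishing probability, and redrawing keeps the number of resamples exact.
Condition comparisons (e.g. high- vs low-amplitude sampling at matched
thresholds) use the two-tailed Wilcoxon signed-rank test on the paired
bootstrap series with Bonferroni correction across thresholds; an all-zero
difference vector is reported as p = 1 with a degeneracy flag rather than
an error.

## Prediction under nested, grouped, confound-consistent CV

Features are the per-subject FC edge vectors (averaged over all four runs).
The primary model is kernel ridge regression with a *Pearson kernel*:
`K(a, b)` is the correlation between the two subjects' edge vectors, used
directly as the Gram matrix (no additional centring; the intercept is
handled by centring the targets). The dual solve is
`(K + alpha I) c = y - mean(y)`; the printed candidate grid for `alpha`
runs from 0 to 1e6 (39 values), and `alpha = 0` receives a fixed 1e-10
jitter instead of being excluded.

The outer split is 10-fold with families never split across folds
(assignment is greedy: largest family to the currently smallest fold, with
seeded random tie-breaking); a repeated plain k-fold scheme (5 folds, 5
repeats) covers unrelated cohorts. Hyperparameters are selected by a 5-fold
inner loop on each training set, maximising inner-validation Pearson r
(regression) or accuracy (classification); ties resolve to the smallest
grid value, which favours the least regularised of equally scoring models
deterministically. The inner fold count shrinks automatically when a small
training set cannot support five grouped folds.

Confound handling is CV-consistent everywhere: for regression targets an
OLS model of the target on age, sex and mean framewise displacement (plus
intercept) is fit on the training partition only and its coefficients
applied to both partitions — including inside the inner loop. For binary
classification residualising the label is not meaningful, so the confounds
are regressed from the *features* instead, again train-fitted per split;
this is the one place the regression and classification recipes diverge,
and it is a deliberate design choice documented here. The returned
`fold_details` expose every fitted coefficient so leakage can be audited:
permuting a fold's test targets must change nothing that was fitted for
that fold, and the acceptance suite asserts exactly that.

CBPM screens edges by train-only correlation with the target (two-tailed
unadjusted p < 0.01 by default, configurable), sums the surviving positive
and negative networks per subject, and fits a two-regressor linear model.
With no surviving edge it falls back to the train-mean intercept, flagged.
The ridge classifier is Pearson-kernel ridge on ±1 labels with a sign
decision — the kernel analogue of the usual least-squares ridge
classifier, sharing the regularisation grid with the regressor.

Scores: Pearson r, R², MAE for regression; accuracy and balanced accuracy
(mean of sensitivity and specificity) for classification.

## ROPE comparison of cross-validated models

`rope_compare()` implements the Bayesian correlated t-test for
cross-validation results: the posterior of the mean paired fold difference
is Student-t with location `mean(d)`, scale
`sqrt((1/k + n_test/n_train) * var(d))` and `k - 1` degrees of freedom.
The `n_test/n_train` term is the Nadeau–Bengio correction for the overlap
of CV training sets; setting `correlated = FALSE` gives the plain paired
posterior (the closed-form limit as `n_test/n_train -> 0`, asserted in the
tests). The three probabilities are the posterior mass left of, inside,
and right of the equivalence region; the default half-width 0.05 means a
5-point accuracy difference (or 0.05 correlation units) is practically
equivalent. The decision symbol is the region with the largest mass, ties
resolving to "=". Zero-variance differences give a degenerate but defined
answer (all mass in the region containing the mean).

## Preprocessing

The nuisance design is the standard 12-parameter recipe: WM, CSF and GS
means, each with its square, its backward-difference temporal derivative
(first element 0, length-preserving) and the squared derivative, plus one
binary spike column per frame with FD above 0.25 mm. Spike columns are
extras beyond the 12-parameter count. Cleaning follows the sequence
detrend → zero-phase Butterworth bandpass (order 5 per pass, default
0.008–0.08 Hz) → least-squares confound regression, with the continuous
design columns detrended and filtered identically before regression so the
removal cannot re-introduce out-of-band signal and the residuals are
exactly orthogonal to the processed design; spike indicators stay binary.
Order-5 forward–backward Butterworth filtering is numerically stable at
this band for TRs of 0.7–1 s (verified by periodogram: ≥ 90% attenuation
at 0.2 Hz, in-band signal preserved). Rank-deficient designs drop
collinear columns with a warning. Cleaning is off by default for synthetic
cohorts, which are generated clean.

Run trimming takes head/tail counts as explicit arguments (e.g. 20 and 18
frames, turning a 478-frame run into 440 frames divisible into 8 bins of
55) rather than assuming an acquisition length.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws each run as `x(t) = g(t) * L_s u(t) + e(t)`:

* **Stable subject fingerprints.** `L_s` is the Cholesky factor of the
  subject's true correlation matrix, a blend of one population matrix with
  family- and subject-level random perturbations weighted by
  `subject_snr`. At `subject_snr = 0` all subjects are statistically
  identical (identification must fall to chance); large values make the
  fingerprint dominate (identification must reach 1). Family members share
  the family perturbation, so grouped CV differs measurably from plain CV.
* **Co-fluctuation events.** `g(t)` is 1 outside and `1 + event_amplitude`
  inside Poisson-placed bursts (default rate 3 per run, 5 frames long).
  The gain is *multiplicative on the shared latent signal*, so events
  raise co-fluctuation brain-wide — the construct RSS is designed to
  detect — rather than adding spikes to single parcels.
* **Motion.** FD traces are positive AR(1) noise (mean 0.12 mm, lag-1
  coefficient 0.6), independent of `g(t)` by default so the RSS–FD
  diagnostic centres on zero; `rss_fd_coupling > 0` induces a correlation
  for testing the diagnostic's sensitivity.
* **Phenotypes.** Each target is `effect_size` times a standardised linear
  combination of the subject's *true* FC edges, plus `confound_weight`
  times a standardised age/sex/FD mix, plus Gaussian noise (sd defaults to
  1; 0 gives a noise-free target for recovery tests).
* **Structural connectivity.** Per-subject streamline counts are Poisson
  draws around a profile affine in the population FC, giving every subject
  a positive SC–FC coupling by construction.

Deliberately *not* emulated: haemodynamics, autocorrelated BOLD spectra,
physiological noise structure, non-Gaussian tails, parcel-size effects,
scanner drift. Passing recovery tests therefore shows the *estimators* are
correct under the assumed generative structure, not that real data meet
those assumptions. Defaults (TR 0.72 s, 4 runs over 2 days, 2 encodings)
mirror the resting-state regime the pipeline targets.

## Problem sizes and numerical choices

The recovery analyses use cohort sizes chosen so every statistical claim
is comfortably powered at desk scale: fingerprint recovery uses 60
subjects × 100 parcels × 1200 frames (high-SNR and zero-SNR cohorts; the
chance band is the binomial 95% interval around 1/60 over the 120 directed
identification trials); prediction recovery uses 200 subjects × 15 parcels
× 1200 frames with a dense noise-free target (all 105 edges informative)
and a 20-seed null. The 15-parcel choice reflects a property of the
Pearson kernel worth knowing: its row-standardisation cannot represent an
arbitrary linear functional of the edges, so with many more edges than
subjects even noise-free targets plateau below r ≈ 0.9; with edge counts
below the subject count the kernel recovers dense linear targets almost
perfectly. Other constants: Cholesky factorisation adds a 1e-10 ridge;
constant parcels in a frame subset yield zero correlations with a warning
(keeping the estimate defined rather than NA); FC averaging is on raw
correlations (Fisher-z averaging available via a flag, off by default
since the downstream metrics are themselves correlation-based).

## Known limitations

Bootstrap confidence intervals are percentile intervals, not BCa. The
grouped fold balancer optimises fold sizes greedily, not optimally (exact
balance is NP-hard; the greedy gap is at most one family). The pipeline
computes any requested subset of bins; which intermediate bins are most
informative is an empirical question the synthetic generator is not
designed to answer — its events make high-amplitude frames *more*
subject-diagnostic, the regime the estimators must handle, not a claim
about real brains.
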