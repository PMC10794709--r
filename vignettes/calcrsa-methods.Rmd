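---
title: "Methods: time-resolved representational analyses of approximate mental calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved representational analyses of approximate mental calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcrsa)
```

## The problem

When a person sees a cloud of dots, is cued to multiply or divide its
numerosity by 2 or 4, and holds the internally computed result in mind over
a delay, four partially correlated aspects of the computation are
represented in the brain at overlapping times: the stimulus-evoked *sample*
numerosity, the *operation*, the *operand*, and the internally generated
*result* numerosity. `calcrsa` implements the analysis chain that
disentangles these components in multi-voxel fMRI patterns — a
finite-impulse-response (FIR) GLM for time-resolved response estimation,
multiple regression of neural representational dissimilarity matrices
(RDMs) on four predictor RDMs, cross-temporal decoding between sample and
result codes, psychometric estimation of behavioral precision, and group
inference — together with a synthetic BOLD + behavior generator with known
ground truth, so that every stage is testable end to end without any
neuroimaging download.

## The design and its predictors

Each 20 s trial presents a sample of 6, 12, 24 or 48 dots at 0 s, a
multiply/divide-by-2-or-4 cue at 2 s, and a probe dot cloud at 12 s that
requires a smaller/larger judgment against the computed result. On 20% of
trials (catch trials) the probe arrives early, uniformly in 5.4–9.6 s, to
force immediate computation; catch trials are modeled in the GLM but never
analyzed. A sample × operation × operand combination is a condition only if
its exact result is itself in {6, 12, 24, 48} (`build_conditions()`); this
closure rule yields exactly 10 conditions, 5 per operation.

The four predictor matrices (`build_predictor_rdms()`) hold
`|log a − log b|` for sample and result numerosities and 0/1 dissimilarity
for operation and operand. With this condition set the sample and result
predictors correlate −0.34 and are exactly equally correlated with the
operation predictor — the property that makes the unique contributions
separable in a joint regression. All downstream results are invariant to
the log base and to the categorical constant because every matrix is
z-scored before regression (asserted by tests).

## The synthetic-data generator

`make_voxel_population()` + `simulate_bold_run()` emulate what the analysis
needs from real data, not the physics of acquisition.

**Numerosity codes as an explicit representational geometry.** The four
log-spaced numerosity levels are embedded as points in pattern space with a
fixed, compressively saturating geometry (`level_geometry()`): adjacent
levels at graded squared distances 1 : 1.36 : 1 and all level pairs two or
more steps apart saturating near 3.03 — a monotone, log-scale magnitude
code with the long-range compression typical of numerosity similarity
gradients. Each condition also carries an identity component whose energy
equalizes the centered pattern norms across conditions. This calibration
was done once, analytically, with a specific purpose: the analysis measures
`1 − Pearson` distances of mean-centered patterns, and for any code whose
conditions sit at unequal distances from the pattern centroid the
normalization distorts the measured dissimilarities with condition-specific
("radius") terms that are not spanned by the four predictors and would leak
systematic pseudo-effects into the categorical predictors. Norm
equalization removes the noise-level dependence of that distortion exactly
(equal norms rescale uniformly at any measurement noise), makes the
dissimilarity structure of mixed sample/result activity a linear
combination of the two codes' structures, and the remaining fixed
projection onto the operation/operand predictors is minimized over the
admissible monotone geometries (residual regression weights ≈ +0.02 and
−0.04 against ≈ +0.8 for the true predictor). A deliberately naive
alternative — a rank-1 code `value × weight vector` — produces spurious
operation effects with group *p* < 0.001 at *n* = 17; that is a property of
correlation-distance RSA, not of this package, and the generator is built
so its ground truth respects the analysis's specificity contract.

**Subspace sharing.** The result code reuses the same level embedding on a
voxel basis mixed as `share · B_sample + √(1 − share²) · B_independent`, so
`subspace_share = 1` means a numerosity evokes the same pattern whether
perceived as sample or computed as result (a shared representational
space), and 0 means orthogonal subspaces. Cross-decoding transfer scales
with this parameter by construction; the correlation between the leading
sample and result code directions equals it exactly.

**Temporal envelopes.** Envelopes are neural-level activity profiles
convolved with a canonical double-gamma HRF (peak ≈ 5 s). The sample code
is a stimulus-evoked transient (0–1.6 s), so its BOLD response peaks in the
middle of the delay (4–8 s); the result code ramps up from 3 s — after the
2 s cue — and is sustained to the probe, so its BOLD response dominates the
late delay (8–12 s). Stating the windows at the BOLD level (rather than
giving the neural envelopes themselves mid/late peaks) is deliberate: the
HRF shifts any neural profile by roughly 5 s, and the analysis windows are
defined on the measured signal. Operation and operand codes are cue-locked
transients; no envelope is active before its attribute's earliest causal
event.

**Condition-stable nuisance code.** Real patterns contain reliable
condition-specific structure unrelated to the design predictors (display
idiosyncrasies, strategies). A rank-5 random condition code, redrawn per
subject and active throughout the delay, supplies this between-subject
scatter; it averages out at the group level. Its per-condition values are
nearly uncorrelated with both numerosity labels in this design, so it does
not masquerade as cross-decoding transfer.

**Amplitudes and noise.** Defaults: sample amplitude 1.2 and result
amplitude 2.0 signal units at each code's BOLD peak — the result envelope
reaches only ≈ 0.55 of its peak inside the 8–12 s window, so the two codes
have comparable *effective* in-window strength (≈ 1.1–1.2 units, about 1%
of the baseline of 100) — nuisance amplitude 1.5, AR(1) noise with
ρ = 0.3 and marginal SD 1, three cosine drift components of SD 0.5 per run.
These were chosen once as a realistic weak-pattern regime: group effects at
*n* = 17 reach *t* ≈ 7–12 for embedded codes (comparable to strong real
effects), while single subjects are noisy, and cohorts with no embedded
code test at nominal false-positive rates.

**Behavior.** `simulate_observer()` responds "larger" with probability
`Φ((log ratio − PSE)/σ)`, `σ = weber/Φ⁻¹(0.75)`, so `weber` is the
just-noticeable difference on the natural-log scale; a per-operation PSE
shift implements operational-momentum scenarios. Behavioral noise is
response-level only; there is no explicit calculation-noise stage.

What the generator does **not** emulate: physiological noise and motion,
spatial autocorrelation of noise, surface geometry, visual dot rendering,
scanner drift nonstationarity. Passing tests therefore certify the
analysis chain's correctness and calibration on data with known structure,
not robustness to every artifact of real acquisitions.

## FIR GLM

`build_fir_design()` places one 0/1 stick per condition × 2 s bin (10 bins,
one TR each), a pooled catch condition, per-run discrete-cosine drift with
a 244 s cutoff, per-run constants, and optional confound columns. Because
the 10-bin FIR window exactly tiles the 20 s trial spacing, the condition
sticks of a run sum to that run's constant; this structural aliasing is
detected and the constant is dropped at fit time (`fit_fir()`, pivot order
sticks first), which absorbs the baseline into the FIR estimates — harmless
because every downstream pattern analysis centers across conditions. Any
other collinearity is an error naming the offending columns. Estimation is
voxel-wise OLS; AR(1) prewhitening with a pooled coefficient is available
behind a flag but off by default, since OLS estimates are unbiased and the
downstream contracts do not depend on whitening. Per-run fitting
(`mode = "per_run"`) provides the independent pattern estimates that
leave-one-run-out decoding requires.

## RSA

`neural_rdm()` subtracts each voxel's mean across the 10 analyzed
conditions and computes `1 − Pearson` distances; degenerate (zero-variance)
patterns yield flagged undefined entries, and searchlight centers with such
entries or fewer than 2 in-mask voxels are skipped, not imputed.
`rdm_regression()` z-scores the 45-element vectorized strict upper
triangles of the neural and the four predictor matrices and fits an
ordinary multiple regression; the intercept is included so the result is
invariant to the neural vector's mean (with both sides z-scored it is ≈ 0
anyway). `searchlight_rsa()` repeats this in spheres of radius 3 voxels
(123 voxels in the interior, boundary included, center included).
`window_average()` averages bins 1–2 (early, 0–4 s), 3–4 (middle, 4–8 s),
5–6 (late, 8–12 s); bins are 1-based, bin *k* covering (k−1)·2 to k·2 s.

## Cross-temporal decoding

`fit_predict_numerosity()` trains a linear support vector regression
(`e1071::svm`, C = 1; the insensitivity width ε is unstated in common
practice references so it defaults to the conventional 0.1, configurable)
on run-wise FIR patterns, labels being the z-scored log numerosity of the
sample or result, under leave-one-run-out cross-validation. Features are
voxel-wise z-scored across conditions within the training set and within
the test set separately (recomputing rather than reusing training
statistics; the alternative is available behind `scale_test = "train"`).
The score is the Fisher-z-transformed Pearson correlation between true and
predicted labels, averaged over folds; correlations are clipped away from
±1 before `atanh`, and folds with constant predictions score 0 (logged)
so subject averages stay defined. `cross_decoding_cells()` implements the
window of interest: sample bins 2–4 (2–8 s) × result bins 4–6 (6–12 s),
non-overlapping and separated by at least one bin — exactly 6 cells per
train direction; `cross_decoding_score()` averages both directions (12
cells), with the direction choice exposed through the two matrices.

## Psychometrics

`fit_psychometric()` fits `P(larger) = λ + (1 − 2λ)·Φ((log r − PSE)/σ)` by
maximum likelihood (binomial, per-ratio counts) with a fixed grid of
starting values feeding L-BFGS-B, so the fit is deterministic. The lapse λ
is fixed at 0 by default (a free-lapse fit is behind a flag). The JND is
`σ·Φ⁻¹(0.75)`, the standard convention for ratio-based numerosity
comparison, and log-scale JND and Weber fraction are used interchangeably.
σ is bounded in [0.001, 25]: perfect separation clamps it at the floor and
chance-level responding drives it to the ceiling, both flagged as boundary
fits with a warning. `operational_momentum()` is a paired two-tailed t test
of division versus multiplication PSEs with Cohen's d; pooled-operation
fits are the default for Weber fractions, per-operation fits are available
through the filter argument.

## Group statistics

`cluster_permutation()` adapts surface-based cluster permutation to the
synthetic volumetric grid: two-tailed one-sample t maps are thresholded at
the cluster-forming p (0.01), suprathreshold voxels grouped into
6-connected components separately for positive and negative effects
(cluster extent as the statistic, the closest volumetric analog of vertex
counts), and each observed extent compared with the permutation null of
the maximum extent under random sign flips of whole subject maps — the
standard one-sample permutation scheme. Permutation p values are
`(1 + #{null ≥ obs})/(n_perm + 1)`, never 0. `bh_fdr()` applies
Benjamini–Hochberg step-up over the whole input family (for ROI RSA: all
32 subregions × 2 windows). `brain_behavior_correlation()` computes
Pearson correlations between subject-wise cross-decoding scores and Weber
fractions with the t-transform p value and FDR across ROIs.

## Problem sizes used by the test suite

The package's checks run at desk scale, chosen so the full suite completes
in minutes on one CPU while keeping each claim statistically meaningful:
the main recovery cohort uses 17 subjects on a 20×20×20 grid with a 5×5×5
coding region and 6 runs; specificity replication uses 10 cohorts of 17
subjects at ROI size (125 voxels); null calibration uses 200 cohorts at
the response-estimate level (with no embedded code the FIR estimates are
exchangeable noise, so this isolates the RSA + group stage the claim is
about); decoding monotonicity uses 5 share levels × 20 seeds at noise SD
0.5, where the transfer gradient is well resolved; cluster-permutation
FWER calibration uses 100 null cohorts at 200 permutations; psychometric
type-I calibration uses 200 equal-shift cohorts. `run_pipeline()` defaults
mirror the cohort conditions (17 subjects, 6 runs, 20×20×20 grid) with the
searchlight + cluster stage behind a flag, since ROI statistics carry the
standard summary.

## Known limitations

Correlation-distance RSA of low-dimensional magnitude codes has an
irreducible, small projection onto correlated categorical predictors; the
generator minimizes it by construction, but analyses of codes with strongly
unequal condition norms should expect such leakage (the reason the
generator's geometry is documented rather than hidden). The SVR transfer
score is a biased-down estimate at low SNR (constant-prediction folds score
0). The cluster permutation assumes spatially exchangeable noise under sign
flips, which the generator satisfies but real data only approximate.
Decoding and RSA share the same FIR estimates; no bias results, but their
errors are correlated across stages within a subject.
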