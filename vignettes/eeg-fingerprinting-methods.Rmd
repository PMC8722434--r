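---
title: "Methods: EEG functional-connectivity fingerprinting on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG functional-connectivity fingerprinting on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Resting-state EEG functional connectivity — the pattern of statistical
coupling between scalp electrodes — appears to be subject-specific enough to
act as a "brain fingerprint": a classifier trained on one person's
connectivity patterns can pick that person out of a group. Two properties
matter for that claim. *Specificity*: within a single recording session, how
accurately can subjects be identified from short connectivity snapshots?
*Permanence*: does a fingerprint learned on day 1 still identify the subject
weeks or months later, when electrode placement, vigilance and slow
physiological change have all moved the signal?

`eegfp` implements the full analysis chain for both questions — connectivity
estimation, closed-set identification, longitudinal evaluation and
region-level localization of the identifying connections — together with a
synthetic longitudinal cohort generator that provides a ground-truth test
bed, since suitable public longitudinal EEG cohorts are scarce.

## The synthetic cohort

Each subject is a stationary vector-autoregressive (VAR) process over the 32
electrodes of a standard 10/20 montage:

$$x(n) = \sum_{k=1}^{K} A_k\, x(n-k) + \varepsilon(n), \qquad
\varepsilon(n) \sim \mathcal{N}(0, \Sigma).$$

The coefficient tensors share a *backbone* across subjects — damped
per-channel dynamics (lag-1 weights 0.30–0.50, lag-2 weights −0.25 to −0.10)
plus weak dense cross-coupling of scale `base_coupling` = 0.1 — so subjects
are not trivially separable by global dynamics. Individuality comes from
`n_planted` = 12 *planted edges* per subject: directed lag-1 couplings at
subject-specific positions with mean magnitude `planted_strength` = 0.35.
By default the planted edges are confined to intra-frontal channel pairs
(the 11 electrodes Fp1–FC6), giving the region-localization stage a known
ground truth; the pool is configurable. Stability is enforced by shrinking
the tensor until the companion-matrix spectral radius is ≤ 0.95 (with the
default knobs no shrinking triggers, so backbones stay bit-identical across
subjects).

Sessions A–F sit on nominal days 1, 2, 7, 30, 90 and 180. Session-to-session
change is modelled as an elementwise fractional coefficient perturbation
$A' = A + \delta \cdot |A| \odot Z$, with $Z$ standard normal drawn once per
subject-session and $\delta = c\,\log(\mathrm{day})$. Scaling the
perturbation by each coefficient's own magnitude keeps the coupling
structure (zeros stay zero) while degrading the subject-distinctive values
in proportion to the day gap. No generative model of day-to-day EEG change
is established in the literature at this level of abstraction; monotone
log-day drift is the minimal structure that produces the qualitative
phenomenon of interest — identification accuracy that decays with the
training–test day gap while day-1 data are drift-free. The constant is set
to `drift_c` = 0.2, chosen (once) so that the day-180 session loses an
appreciable share of identification accuracy rather than saturating at
ceiling; it is a knob of the simulator, not an estimate of human
physiology. Because each session draws a single perturbation direction, a
given session can land closer to or farther from the day-1 model than its
day gap alone predicts; the permanence curve is monotone in expectation
(and in multi-seed means), not seed by seed.

Recordings are 4-minute resting blocks. The simulator's default sampling
rate is 250 Hz rather than the 1000 Hz typical of acquisition hardware: a
2-s epoch still spans 500 samples, which comfortably supports the order-15
bivariate fits downstream, and the whole pipeline then runs at desk scale.
`fs` is configurable where acquisition-rate parity matters. White,
channel-independent sensor noise of standard deviation `noise_scale` = 0.5
(innovation variance 1) is added after the recursion; no 50 Hz line
component is injected, but the notch stage runs regardless so that the code
path matches what real data would need.

What the generator deliberately does **not** emulate: volume conduction
through a head model (channels mix only through VAR coupling), non-white
sensor noise, artifacts (ocular, muscular), non-stationarity within a
session, and realistic inter-subject variability magnitudes. Passing tests
on this cohort therefore demonstrate that the *pipeline* recovers planted
structure under its own model assumptions — not that real human EEG carries
fingerprints of any particular strength.

## Preprocessing

The chain is fixed: temporal filter → spatial filter → segmentation.

* **Band-pass + notch.** Zero-phase (forward–backward) 4th-order
  Butterworth band-pass, default 1–40 Hz, followed by a zero-phase 2nd-order
  constrained biquad notch at 50 Hz with quality factor 30. Broadband 1–40 Hz
  is used throughout; there is no per-band decomposition.
* **Surface Laplacian.** Each channel is re-referenced to the mean of its
  montage neighbours (Hjorth nearest-neighbour Laplacian) using a fixed,
  documented 10/20 adjacency shipped as a plain-text table. This is a
  deliberate substitution for spherical-spline current-source-density
  methods: it needs no head model, is linear and local, and achieves the
  same qualitative goal — attenuating the volume-conducted common component
  that would otherwise inflate inter-channel coupling. It is applied to the
  continuous recording, before segmentation.
* **Segmentation.** Non-overlapping 2-s epochs; the trailing partial
  segment is dropped. A 240-s session yields 120 epochs; epochs keep their
  subject and session labels.

Independent-component artifact rejection is out of scope (synthetic data are
artifact-free); `preprocess_recording()` exposes an `artifact_hook` slot
where externally cleaned real data can be injected.

## Connectivity indices

**Granger causality (GC).** For each ordered electrode pair, the *full*
model is the bivariate AR fit above; the *restricted* model regresses a
channel on its own `p` lags only. The index is

$$GC_{y \to x} = \ln \frac{V_{x|\bar{x}}}{V_{x|\bar{x},\bar{y}}},$$

the log-ratio of restricted to full residual variance — zero when the other
channel's past adds no predictive information, positive otherwise. Model
order `p` = 15. Conventions the formulas leave open are fixed as follows:
both models are estimated by OLS without intercept over the common window
`n = p+1..N`; residual variances are means of squared residuals (1/M over
the M = N − p fitted samples); both variances are floored at 1e−12 before
the ratio; and tiny negative estimates (possible only through solver
round-off, since the models are nested) are clipped to zero. GC is computed
*pairwise*, not conditionally on the remaining 30 channels — the defining
equations are strictly bivariate. Per epoch this gives a directed 32 × 32
matrix; it is flattened row-major into a 1024-long feature vector with the
32 diagonal self-pairs fixed at 0 but retained, keeping the feature count at
32².

The per-epoch matrix runs in compiled code (RcppArmadillo): the lag
cross-product matrix is built once per epoch and every pair then costs one
symmetric 2p × 2p solve with two right-hand sides. The R-level per-pair
functions (`fit_bvar()`, `granger_causality()`) implement the same
estimator via QR and are cross-checked against the compiled path in the
tests.

**Mutual information (MI).** The plug-in histogram estimator of

$$MI_{xy} = \sum_{i,j} p(x_i, y_j)\,
\log \frac{p(x_i, y_j)}{p(x_i)\,p(y_j)}$$

with 16 equal-width bins per axis over each series' observed range, logs in
base 2 (bits), and empty cells contributing zero. The estimator family, bin
count and base are configurable; no claim of numerical parity with any
particular toolbox implementation is made, since those settings are not
standardized. Two implementation details worth knowing: cell contributions
are summed in sorted order, which makes `MI(x, y)` and `MI(y, x)`
bit-identical (the cell multiset is transpose-invariant); and binning over
each series' own range makes the estimate invariant under per-series
monotone affine maps. With 500-sample epochs and 16² cells the plug-in
estimate is strongly positively biased (bias ≈ (B−1)²/(2N ln 2) under
independence); this is uniform across epochs and harmless for
classification, but the per-epoch warning is suppressed in the vectorized
path. MI features are the 496 = 32·31/2 strict-upper-triangle entries.

## Identification

A one-against-one multiclass SVM with RBF kernel: one binary classifier per
subject pair, majority vote at prediction. Features are z-scored per column
with parameters learned on training rows only — an addition the RBF kernel
effectively requires on heterogeneous-scale features — and the kernel width
defaults to 1/(n_features × mean feature variance) with regularization
C = 1. No hyperparameter values are prescribed by the study design; a small
grid over C ∈ {0.1, 1, 10} is available and, when requested, runs inside
training folds only.

*Specificity* is measured by stratified ten-fold cross-validation within one
session: each subject's epochs are shuffled once (fixed seed) and dealt
round-robin over ten folds, so every fold is subject-balanced; accuracy is
pooled over held-out epochs (correct epochs / total epochs — epoch-level,
matching the 9/10-train 1/10-test design). *Permanence* is measured by
training one model on all of session A and scoring sessions B–F in
nominal-day order, scaler and hyperparameters from session A only.

## Localizing the identifying connections

An RBF-kernel SVM has no primal feature weights, and no canonical
formulation exists for extracting per-feature identification scores from
it; the score-extraction step is therefore implemented as two clearly
labelled surrogates. The default trains one binary *linear* margin
classifier per subject pair and aggregates per-feature |w| across all pairs;
the alternative is permutation importance of the RBF model (per-feature
column shuffle, mean accuracy drop over r repeats). "Major connections" are
the top 10% of valid features by weight — diagonal GC self-pairs are never
valid, so for GC that is round(0.10 × 992) = 99 directed pairs, for MI
round(0.10 × 496) = 50 undirected pairs. Ties at the boundary go to the
lower feature index. The selected pairs are tabulated into a 5 × 5 scalp
region matrix (frontal, central, temporal, parietal, occipital; intra-region
counts on the diagonal; directed pairs count from-region × to-region,
undirected pairs fold into the upper triangle), and the intra-frontal
fraction is compared against the uniform-selection baseline
11·10/(32·31) ≈ 0.111 for directed pairs.

The region map follows standard 10/20 nomenclature prefixes — frontal:
Fp1, Fp2, F7, F3, Fz, F4, F8, FC5, FC1, FC2, FC6; central: C3, Cz, C4, CP5,
CP1, CP2, CP6; temporal: T7, T8, A1, A2 (ear electrodes grouped by
proximity); parietal: P7, P3, Pz, P4, P8, PO3, PO4; occipital: O1, Oz, O2 —
and is overridable through the plain-text montage file.

## Numerical choices and degenerate inputs

* Constant or collinear inputs to the AR fits raise a singular-fit error
  (zero-variance check plus QR rank check); `connectivity_dataset()` skips
  failing epochs with a message and aborts if more than 10% fail.
* Constant inputs to MI return 0 with a warning (degenerate marginal).
* The variance floor (1e−12) prevents −∞ log-ratios on near-deterministic
  pairs; the nonnegativity clip is asserted in tests to act only below
  1e−9 in magnitude.
* Fold assignment, cohort generation and every stochastic step derive from
  explicit integer seeds; the full experiment is a pure function of one
  master seed, and reruns produce byte-identical feature files and reports.

## Problem sizes

Two shipped profiles fix the problem sizes used throughout.
`full_profile()` is the full study design: 15 subjects × 6 sessions ×
120 two-second epochs at 250 Hz, order-15 GC (1024 features), 16-bin MI
(496 features), ten-fold CV. `quick_profile()` — 5 subjects, 40 epochs per
80-s session at 125 Hz, order-8 GC — exists because the full grid is worth
its runtime only for the headline numbers; the reduced profile preserves
every structural property (montage, feature dimensions via 32 channels,
session schedule, drift law) at roughly a fiftieth of the compute. The test
suite exercises the full-scale profile for the single-session specificity
result and the reduced profile for multi-seed properties (permanence
monotonicity, separability monotonicity, chance-level controls).

## Known limitations

* The synthetic cohort is a VAR world: linear, stationary within session,
  Gaussian. Nonlinear coupling — the regime where MI should beat GC — is
  not represented, so comparisons between the two indices on this cohort
  say nothing about their relative merit on real EEG. Relatedly, MI here
  captures the planted linear couplings only weakly at reduced problem
  sizes, so MI identification accuracies trail GC on synthetic data.
* Real-data ingestion (EDF/BrainVision) is not implemented in this version;
  the preprocessing chain accepts any `eeg_recording` built from an
  externally loaded channel × sample matrix with a matching montage.
* The Hjorth Laplacian is a coarser spatial filter than spherical-spline
  CSD; with the shipped adjacency it is a fixed linear operator, which is
  exactly what the tests rely on.
* Identification is closed-set only; verification-style metrics (impostor
  scores, equal error rate) are out of scope.
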