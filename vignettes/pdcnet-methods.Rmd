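---
title: "Methods: PDC effective connectivity and SVM cohort classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDC effective connectivity and SVM cohort classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pdcnet implements a resting-state EEG classification analysis built on
effective (directed) connectivity: multichannel recordings are cut into
2-second segments, each segment is modelled as a multivariate
autoregression (MVAR), the model's spectral transform yields partial
directed coherence (PDC) adjacency matrices over a 64-band frequency grid,
and support vector machines classify two cohorts (an AUD-like positive
class versus a control-like class) from those matrices, band by band,
rhythm by rhythm, and after ANOVA-based feature reduction. Because clinical
EEG of this kind is typically access-restricted, the package ships a
synthetic cohort generator with *known* ground-truth connectivity; every
claim the test suite makes is checked against that ground truth.

## The model

A segment of \(S\) channels is modelled as an order-\(\rho\) MVAR,
\[
y(t) = \sum_{\zeta=1}^{\rho} C_\zeta\, y(t-\zeta) + \epsilon(t),
\]
with \(S \times S\) coefficient matrices \(C_\zeta\) (row = target channel,
column = source channel) and Gaussian innovations
\(\epsilon(t) \sim \mathcal N(0, \Sigma_\epsilon)\). Stationarity is
checked through the companion matrix: all its eigenvalues must lie strictly
inside the unit circle. The frequency-domain coefficient matrix is
\[
\bar A(\omega) = I - \sum_{\zeta=1}^{\rho} C_\zeta e^{-j\omega\zeta},
\]
and squared PDC from source \(w\) to target \(v\) is the column-normalized
squared magnitude
\[
\Psi^2_{vw}(\omega) =
\frac{|\bar A_{vw}(\omega)|^2}{\sum_{v'} |\bar A_{v'w}(\omega)|^2}.
\]
Two identities make PDC attractive as a directed-connectivity measure and
as a test target: each source column sums to exactly 1 at every frequency,
and a structurally absent coupling (\(c_{vw}(\zeta)=0\) for all lags,
\(v \neq w\)) gives exactly zero — Granger nullity. Both are asserted in
the suite, analytically and on estimated models.

We use the squared, column-normalized form throughout because it is
bounded in \([0,1]\) and is the standard normalization for this measure;
the magnitude form \(|\Psi|\) is available via `squared = FALSE`.

## Frequency grid and rhythms

The analysis range 0.1–70 Hz is tiled by 64 equal bands of width
\((70-0.1)/64 \approx 1.092\) Hz. A band's PDC value is the mean of squared
PDC over `k_per_band = 4` equally spaced frequencies inside the band
(sub-interval midpoints); point evaluation at a single frequency is the
`k_per_band = 1` special case. Band values are band-averages of
column-normalized quantities, so source columns of a band matrix sum to
approximately — not exactly — one, and dropping the reference node makes
the sums sub-unity; exact unity holds pre-exclusion at single frequencies,
and the suite checks both regimes.

The five conventional rhythms map onto band indices as delta 1–6, theta
7–12, alpha 13–19, beta 20–47, gamma 48–64. The map is a partition of
1..64, which the suite asserts.

## Pipeline stages and their parameters

* **Standardization** (`standardize`): polyphase rational resampling to
  256 Hz (500 → 256 Hz is exactly 64/125) with a long windowed-sinc
  anti-aliasing FIR, and nanovolt-to-microvolt conversion. Upsampling is
  refused rather than silently interpolated. The FIR half-length is
  10·max(p, q) taps, which keeps passband gain errors well under the 1%
  the tests demand.
* **Filtering** (`filter_signal`): 4th-order Butterworth band-pass
  0.1–70 Hz applied forward–backward (zero phase), then a second-order IIR
  notch at 50 Hz with quality factor 30, also zero-phase. The band-pass
  design and notch Q are common EEG defaults and are arguments, not
  constants.
* **Segmentation** (`segment_recording`): contiguous, non-overlapping
  2-second windows (512 samples at 256 Hz); a trailing remainder is
  discarded. A 5-minute recording yields exactly 150 segments.
  `reject_segments` drops any segment whose absolute amplitude exceeds a
  threshold (default 100 µV when used on real data); it is off for
  synthetic cohorts, which contain no artifacts.
* **MVAR fit** (`fit_mvar`): per-segment ordinary least squares with a
  shared lagged regressor matrix, reference electrode (Cz) dropped first
  so a 19-channel montage yields an 18-node network. `order = "auto"`
  minimizes the multivariate BIC over 1..20; the package's reference
  analyses and the test suite fix `order = 5` for reproducibility, since
  order selection on 512-sample segments adds run-to-run variance without
  changing any of the conclusions the suite checks.
* **Features** (`extract_features`, `vectorize`): each band's 18×18 matrix
  is flattened row-major (target-major) to a 324-length vector; diagonal
  self-connectivity entries are retained. The flattening is exactly
  invertible, and entry (v=2, w=1) lands at index 19 — both asserted.
* **Selection** (`pool_band_values`, `anova_select`): per-connectivity
  two-group one-way ANOVA on segment-level values, thresholding *raw*
  p-values (no multiple-testing correction — the selection is a
  feature-reduction device, not an inferential claim). When selecting over
  a rhythm, a connectivity's values are first averaged across the rhythm's
  bands, one pooled value per segment. Averaging rather than stacking
  bands as extra observations is deliberate: neighbouring bands of the
  same segment are strongly correlated, and stacking would inflate the
  effective sample size and destroy the type-I calibration that the
  acceptance suite verifies on null cohorts. For two groups F equals the
  squared pooled t statistic; the implementation computes that vectorized
  across the 324 connectivities and is cross-checked against `aov` in the
  tests. Zero-variance connectivities get p = 1 by convention, with a
  warning.
* **Classification** (`tune_svm`, `evaluate_svm`, `per_band_sweep`):
  SVMs via e1071/libsvm. Hyperparameters (kernel ∈ {gaussian, polynomial,
  linear}; box constraint log-uniform 1e-3..1e3; Gaussian scale
  log-uniform 1e-2..1e2; polynomial degree 2–4) are tuned by a seeded
  sequential search maximizing k-fold CV accuracy within a fixed budget
  (default 30): ~60% random exploration, then Gaussian refinement around
  the incumbent in log-space. Any budget-respecting global optimizer
  satisfies the same contract; this one was chosen because it is simple,
  fully deterministic given the seed, and needs no surrogate-model
  machinery. Evaluation is repeated stratified k-fold CV (default 5×5);
  accuracy is reported mean ± sd over repeats, confusion counts accumulate
  over all held-out folds, and the ROC pools held-out decision scores. The
  operating point maximizes Youden's J = TPR − FPR. AUC is trapezoidal and
  equals the normalized Mann–Whitney U, which the tests use as an
  independent oracle.

### Split policy and leakage

The default split stratifies *segments*, so one subject's segments can
appear in both training and test folds. This mirrors the segment-level
protocol the analysis emulates, but it is optimistic whenever features
carry subject-specific structure: the classifier can partially memorize
subjects. `split = "subject"` keeps each subject's segments in a single
fold and is the recommended setting for real cohorts. The suite
demonstrates the leakage directionally: on synthetic feature tables with
strong subject offsets and a weak class signal, segment-split accuracy
exceeds subject-split accuracy in the large majority of seeded cohorts.

## The synthetic cohort generator

`cohort_config()` defaults encode the emulated study conditions: 35
subjects per class, 5-minute 19-channel recordings at 256 Hz on the 10–20
montage. Both classes share a sparse order-3 backbone (self-dynamics
0.4/−0.15/0.05 at lags 1–3 on every channel, plus 24 seeded random lag-1
couplings of magnitude 0.12); AUD-like subjects additionally receive a
class effect, and every subject's coupling entries are jittered with
Gaussian noise (sd 0.02) to create between-subject variability. Jitter is
restricted to the class-effect entries and lag-1 self-terms so stability
control stays tractable; a jitter draw that destabilizes a model is
redrawn up to 20 times, then reported as an error naming the subject.
All per-subject seeds derive deterministically from the config seed, so a
config reproduces its cohort bit for bit.

The default class effect is frequency-localized by construction: for each
affected directed pair, a symmetric 5-tap coupling filter whose amplitude
response is \(\mathrm{strength}\cdot(\cos\omega - \cos z_1)(\cos\omega -
\cos z_2)\) with zeros at \(z_1 = 0\) (killing the slow delta/theta end)
and \(z_2 = 1.1\) rad/sample (suppressing beta just below gamma). The
response therefore ramps up across the gamma bands of the grid, and the
analytic between-class PDC difference is maximal there — the property the
band-localization checks exploit. Three directed pairs (7←5, 8←6, 4←3 in
montage order) carry the effect at unit strength.

What the generator does *not* emulate: 1/f background spectra, alpha
peaks, eye-blink or EMG artifacts, non-Gaussian innovations,
non-stationarity within a recording. Passing tests show the pipeline
recovers known MVAR-generated structure; they do not certify performance
on clinical EEG, whose within- and between-subject variability is richer.

## Numerical choices

* Stability: companion spectral radius < 1; validated covariances must be
  symmetric within 1e-10 and positive definite.
* Simulation starts from a zero state and discards a 1000-sample burn-in,
  enough for the transient of any accepted (radius < 1) model to decay.
* OLS rank deficiency raises an error naming the segment; fitted models
  are not re-checked for stability (a finite-sample fit may legitimately
  sit near the unit circle) and their residual covariance is symmetrized
  against numerical asymmetry.
* Ties in the per-band accuracy ranking break toward the lower band index;
  ROC tie groups collapse to single points before trapezoidal AUC.
* t-SNE (`tsne_embed`) is the exact O(n²) algorithm with perplexity
  calibration by 50-step binary search, PCA initialization (plus tiny
  seeded jitter to break symmetry), early exaggeration ×12 for 80
  iterations, and momentum/gain-adaptive gradient descent. It exists in
  the package because no t-SNE implementation is available among the
  package's R dependencies; it is adequate for the few hundred segment
  vectors plotted here.

## Problem sizes used by the checks

The reference analyses and automated checks run at reduced, fixed scales
chosen to exercise every stage while keeping runs short: structural
constants on one 5-minute subject; estimator-vs-oracle comparisons on 20
random stable 5-channel models at 2^16 samples (median absolute band
error < 0.02); Granger-nullity on 100 seeded 512-sample segments against
a 1000-segment matched null envelope; ANOVA calibration on a null cohort
of 4 subjects/class × 60 s; classification recovery on 10 subjects/class
× 60 s with tuned SVMs; and band localization over 100 seeded cohorts of
10 subjects/class × 24 s with a 16-band sweep (every 4th band, so five
grid members fall in gamma) using a fixed linear kernel and 2×2-fold CV.
The analysis scripts under `analysis/` use the same scales.

## Known limitations

* The segment-level split is optimistic under subject-level nuisance
  structure; use `split = "subject"` for real data.
* Raw-p thresholding is a reduction device; selected connectivities are
  not individually significant findings.
* BIC order selection on 512-sample, 18-channel segments is noisy; fixing
  the order (default 5) trades bias for reproducibility.
* The generator's MVAR world is a favourable test bed: linear, Gaussian,
  stationary. Real-EEG performance claims require real EEG.
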