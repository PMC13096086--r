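---
title: "freqstate: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{freqstate: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqstate)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and known
limitations. It states no empirical result that the test suite does not
itself compute.

## 1. The microstate model

EEG microstate analysis treats the multichannel scalp potential as a
sequence of brief (tens of milliseconds) quasi-stable topographies. The
analysis assumes (i) that at any moment the scalp field is dominated by one
of a small number of recurring spatial configurations, (ii) that the
polarity of a configuration is irrelevant (the same generator configuration
produces both signs over an oscillatory cycle), and (iii) that moments of
high global field power — the spatial standard deviation across electrodes,

$$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{C}\sum_c \big(v_c(t) - \bar v(t)\big)^2},$$

with divisor $C$ (the channel count) — carry the best signal-to-noise
snapshots of those configurations.

**Segmentation.** Topographies at GFP peaks (strict local maxima; the first
sample of a plateau; no height or distance threshold) are clustered by a
polarity-invariant modified k-means: maps are assigned to the class with the
highest squared spatial correlation, and each class centroid is updated to
the dominant eigenvector of its assigned maps' outer-product sum. Because
the *raw* (unnormalized, hence GFP-weighted) maps enter the update, the
eigenvector maximizes the GFP²-weighted explained variance of its cluster
and every Lloyd iteration is monotone in GEV:

$$\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}_t^2\, r^2(a_{L(t)}, v_t)}
                      {\sum_t \mathrm{GFP}_t^2}.$$

Assignment still uses the normalized correlation, so high-amplitude maps do
not distort class membership — only the centroid estimate, where weighting
by reliability is desirable. This resolves an internal tension in the design
(clustering "on normalized maps" vs. "outer-product-sum" updates) in favor
of the update rule, for the monotonicity just described.

**Model order.** The number of classes is scanned over k = 2–8, reporting
GEV and the predictive-residual criterion

$$\mathrm{CV} = \hat\sigma^2 \left(\frac{C-1}{C-1-K}\right)^2,\quad
  \hat\sigma^2 = \frac{\sum_t \big(v_t^\top v_t - (a_{L(t)}^\top v_t)^2\big)}
                      {T\,(C-1)},$$

the standard criterion for this clustering family (the source analysis does
not print its formula; this is the cited toolbox's convention). The default
mode *reports* the scan and returns a configured fixed k (7 in the emulated
design, matching the uniform choice made there); an automatic elbow (most
negative second difference of GEV) is available by flag, because a
data-driven choice that differs across bands would break cross-band
comparability of the labeled classes.

**Restarts and initialization.** "20 clustering iterations" is read as 20
random restarts (the toolbox meaning), each initialized from K distinct peak
maps, keeping the best final GEV. For tiny instances where the number of
K-subsets of maps is itself small, all distinct subsets are enumerated
instead: random restarts provably cover the initialization space in that
regime, which is what makes exhaustive-search equivalence (acceptance
criterion 2) a property of the implementation rather than of luck.

## 2. Template sorting and back-fitting

Individual-level models are averaged per condition and then into a grand
mean, with polarity alignment (each contributing map is sign-flipped to
correlate positively with a running reference) before re-normalization.
Class correspondence across models is established by sorting against
reference templates: the one-to-one assignment maximizing the summed
absolute spatial correlation, solved exactly by the Hungarian algorithm.
The canonical A–G templates shipped by `canonical_templates()` are
*synthetic geometric stand-ins* built from the textual descriptions of the
normative maps (diagonal gradients for A/B, anterior–posterior for C,
fronto-central maximum for D, left–right for E, occipito-central and
central–posterior maxima for F/G); the normative maps themselves are not
redistributable. They serve to fix a deterministic labeling, not to claim
topographic fidelity.

Back-fitting labels every GFP peak with the best-matching class by absolute
correlation and interpolates between adjacent peaks at the midpoint (the
left segment keeps the extra sample on even gaps). Samples before the first
and after the last peak remain unassigned, and the first and last complete
segments are flagged truncated and excluded from all temporal metrics —
from the duration mean, the occurrence count, and both numerator and
denominator of coverage — so coverage still sums to one.

**A known, quantified bias.** Peak-based labeling cannot see a state that
contains no GFP peak; such states merge into their neighbors. With gamma
dwell times of shape 2 (mean $\mu$) and mean peak spacing $s$, the fraction
of invisible states is roughly $P(d < s) \approx (2s/\mu)^2/2$ for small
$s/\mu$, which inflates mean duration by 2–6% at realistic dwell means
(80–160 ms) *even on noise-free data*. The suite therefore checks noise-free
duration agreement at 2 sample-equivalents (160 ms dwells) rather than 1;
the 10% tolerance of the cohort-scale recovery criterion is unaffected. This
bias is a property of the back-fitting contract itself, not of noise.

## 3. Spectral estimation

The multitaper PSD uses 2-s sliding windows with a 1.5-s hop (the stated
"0.5-s overlap" read literally; the hop is configurable since the phrase is
ambiguous), time–bandwidth product 3, and five Slepian tapers computed from
the classic tridiagonal eigenproblem, combined by concentration-eigenvalue
weighting. The 0.5 Hz grid is restricted to 1–45 Hz. Band powers average
PSD bins inclusively (a bin on a shared edge such as 4 Hz contributes to
both adjacent bands, matching the inclusive band notation; users can shift
edges to get half-open behavior). Wakefulness normalization returns
$10\log_{10}(P/P_\text{wake})$ decibels by default — the standard scale for
anesthesia spectrograms — with a linear-ratio option, since the source
convention states only "wakefulness-normalized". Alpha is 8–15 Hz and beta
15–30 Hz throughout (the Methods convention; some figure captions in the
source print 8–13/13–30, treated as a caption inconsistency).

## 4. The synthetic world

The generator states a world; it is **not** a model of any empirical EEG
distribution, and the source study describes no generative model. Choices,
made once and documented here:

- **State sequence**: semi-Markov, gamma dwell times with shape 2
  (right-skewed, strictly positive — qualitatively matching empirical dwell
  histograms), mean per condition; next state uniform among the other K−1
  (no self-transitions). Defaults: wake 80 ms, LOC 120 ms (× 1.5, the
  slowing effect), ROC 80/1.3 ms (higher occurrence).
- **Topographies**: random smooth maps from a low-order polynomial basis of
  electrode position (dipolar/gradient-like), pairwise |r| < 0.7.
- **Amplitude envelope**: $a(t) = \sum_b \mathrm{amp}_b\,|n_b(t)|$, the sum
  of rectified band-limited Gaussian-noise carriers. The alternative reading
  (rectifying the *sum*) collapses to zero at every carrier zero crossing,
  which floods back-fitting with noise-dominated GFP peaks; the chosen
  reading keeps the envelope bounded away from zero, and its mixture is
  weighted so the GFP peak spacing (~15–20 ms) stays well below dwell times
  — a design constraint of peak-based back-fitting, set before the tests
  were frozen. LOC receives extra delta and alpha carrier weight (the
  anesthetic spectral signature); all conditions carry beta/gamma components.
- **Noise**: spatially and temporally white Gaussian, scaled so the emitted,
  average-referenced recording realizes the requested signal-to-noise power
  ratio (the reference removes a 1/C share of white-noise power, which is
  compensated). Default SNR 4.
- **Between-subject variability**: one log-normal dwell factor per subject
  (SD 0.1), applied to all conditions — so condition *ratios* are preserved
  within subject, as in a repeated-measures design.
- **Determinism**: every random draw derives from the single spec seed via
  fixed integer offsets (all below 2³¹), so cohorts are bit-reproducible.

What a green test does and does not establish: the generator contains no
volume conduction, no 10–20 montage geometry, no artifacts (ocular, EMG,
cardiac), no nonstationarity, and one state sequence shared across bands.
Parameter recovery on this world validates the *pipeline's algebra and
algorithms*, not its behavior on human EEG. In particular, the source
study's observation that combining bands improves classification reflects
band-specific dynamics this generator does not produce; the suite checks
only the weaker direction (adding an informative band does not hurt).

## 5. Statistics

Lilliefors' test (KS distance to a normal with estimated mean/SD) draws its
p-value from a seeded Monte-Carlo null (default 2000 replicates) rather than
lookup tables — the null depends only on n, so it is computed once and
reused. The repeated-measures ANOVA decomposes subject, condition, and error
strata with df = (k−1, (k−1)(n−1)); no sphericity correction is applied by
default (none was reported in the emulated analysis), with Greenhouse–
Geisser behind a flag. Pairwise comparisons are paired t-tests with the
Bonferroni multiplier equal to the number of condition pairs of one metric
within one band — the narrow family named by the stated correction rule.

## 6. Classification

Features are per-class microstate parameters (`duration`, `occurrence`,
`coverage`, `ev`) per band; `ev` is the per-class individual explained
variance (IEV), resolving the source's inconsistent naming of the fourth
parameter (GEV in one section, IEV in another) in favor of the only
per-class variance quantity defined. Standardization is fit on training
rows only, per fold. The NCA weights come from diagonal neighborhood
component analysis (L-BFGS from w = 1, analytic gradient, log-sum-exp
stabilized, penalty λ = 1/n by default; importance = w²); MRMR uses the
greedy mutual-information-difference scheme on 10 equal-frequency bins.
Both score vectors are min–max normalized, summed, and the top 10 features
kept (ties broken by NCA weight, then name). Feature selection runs
*inside* each training fold by default — the leakage-free protocol — with a
"paper mode" flag performing one global selection before CV, mirroring the
likely original procedure; whether the source nested its selection is not
stated.

The linear SVM is one-vs-rest with C = 1 (no tuning was reported), solved
by dual coordinate descent with the bias as an augmented constant feature;
decision values feed pooled-across-folds per-class ROC/AUC (the aggregation
language suggests pooling; per-fold averaging is a trivial variant). The
random forest grows 100 CART trees (Gini, √p features per split, bootstrap
resampling, unlimited depth), with mean leaf vote fractions as scores. Both
are implemented in-package because no SVM or forest implementation is
available in the supported dependency set.

## 7. Numerical choices

- Butterworth band-pass: analog prototype → band-pass transform → bilinear,
  as second-order sections (a 10th-degree polynomial in direct form is
  fragile for a 1 Hz edge at 250 Hz); gain normalized at the geometric-mean
  center frequency; forward–backward application with odd-reflection
  padding of about ten time constants of the slowest pole (10·fs/low
  samples), so the 1 Hz transient dies inside the pad.
- Resampling: rational-factor polyphase with a Kaiser-windowed sinc (10
  taps per phase, β = 5), reflect-padded at the edges.
- k-means convergence: relative GEV change < 1e-7, max 300 iterations;
  empty clusters re-seeded from the worst-fit map; assignment ties take the
  lowest class index.
- Degenerate inputs: constant topographies are rejected (zero GFP has no
  defined GEV); constant feature columns standardize to zero with scale 1
  and are flagged; a class that never occurs reports duration NA,
  occurrence and coverage 0, and is imputed 0 (flagged) in feature tables.

## 8. Known limitations

- The canonical A–G templates are geometric stand-ins (see §2).
- Peak-subsampled back-fitting biases durations upward by a few percent at
  realistic dwell/peak-spacing ratios (quantified in §2).
- EDF support is minimal (16-bit, one record per second, integer rates);
  layouts are not stored in EDF and are regenerated on read.
- The pipeline's statistics and classifier are validated by calibration and
  contract tests on synthetic data; nothing here certifies performance on
  clinical recordings.
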